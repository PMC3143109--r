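# Deterministic synthetic fixtures: hit sets, read pairs, and SAM/BED
# files with known ground truth, for every test surface. Generation uses
# R's Mersenne-Twister with an explicit seed and restores the caller's
# RNG state, so the same spec always yields the same bytes.

#' Describe a synthetic hit set
#'
#' @param seed integer RNG seed; identical spec + seed gives identical
#'   output.
#' @param n number of reads (or read pairs when \code{paired = TRUE}).
#' @param nchrom chromosomes, ids \code{1..nchrom} (names
#'   \code{chr1..chrN} in emitted SAM/BED).
#' @param posrange inclusive range the 5' positions are drawn from.
#' @param strand_frac fraction of reads on the forward strand.
#' @param readlen aligned length given to every read.
#' @param weights \code{"unit"} (all 1), \code{"uniform"} (U(0.1, 2),
#'   float32-rounded), or \code{"multiplicity"} (each read aligns k
#'   places, k uniform on 1..4, yielding k hits of weight 1/k).
#' @param paired generate read pairs instead of single-end reads.
#' @param insert paired-end only: inclusive range of the 5'-to-5'
#'   separation between mates.
#' @return list of class \code{readstore_genspec}.
#' @export
gen_spec <- function(seed = 1L, n = 1000L, nchrom = 1L,
                     posrange = c(1L, 1000000L), strand_frac = 0.5,
                     readlen = 36L,
                     weights = c("unit", "uniform", "multiplicity"),
                     paired = FALSE, insert = c(100L, 300L)) {
  weights <- match.arg(weights)
  if (n < 0) stop("n must be >= 0")
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 nchrom = as.integer(nchrom),
                 posrange = as.integer(posrange),
                 strand_frac = strand_frac, readlen = as.integer(readlen),
                 weights = weights, paired = isTRUE(paired),
                 insert = as.integer(insert)),
            class = "readstore_genspec")
}

with_gen_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate single-end hits with a ground-truth oracle
#'
#' Produces a reproducible hit collection plus closures that answer any
#' region/filter query by brute-force full scan of the in-memory truth,
#' independent of the indexed store path.
#'
#' @param spec a [gen_spec()] (with \code{paired = FALSE}).
#' @return list with \code{hits} (a [single_hits()] data.frame, one row
#'   per alignment; multiplicity k reads contribute k rows sharing a
#'   \code{read} id carried in the \code{read} attribute), \code{reads}
#'   (distinct read count) and \code{oracle}: closures
#'   \code{count(region, filter)}, \code{sum(region, filter)},
#'   \code{hist(region, binwidth, mode, filter)}.
#' @export
gen_hits <- function(spec) {
  stopifnot(inherits(spec, "readstore_genspec"), !spec$paired)
  h <- with_gen_seed(spec$seed, {
    if (spec$n == 0L) {
      hh <- single_hits(); attr(hh, "read") <- character(); hh
    } else {
      mult <- switch(spec$weights,
                     unit = rep(1L, spec$n),
                     uniform = rep(1L, spec$n),
                     multiplicity = sample.int(4L, spec$n, replace = TRUE))
      nh <- sum(mult)
      read <- rep(sprintf("r%06d", seq_len(spec$n)), mult)
      w <- switch(spec$weights,
                  unit = rep(1.0, nh),
                  uniform = float32_round(stats::runif(nh, 0.1, 2.0)),
                  multiplicity = rep(1 / mult, mult))
      lo <- max(spec$posrange[1], spec$readlen)  # keep spans on-chromosome
      hh <- single_hits(
        chrom = sample.int(spec$nchrom, nh, replace = TRUE),
        pos = sample(lo:spec$posrange[2], nh, replace = TRUE),
        strand = ifelse(stats::runif(nh) < spec$strand_frac, "+", "-"),
        length = spec$readlen, weight = w)
      attr(hh, "read") <- read
      hh
    }
  })
  list(hits = h, reads = spec$n, oracle = brute_oracle(h))
}

# Brute-force oracle over an in-memory hit table: the independent
# reference every indexed query is checked against.
brute_oracle <- function(hits) {
  sel <- function(region, filter = hit_filter()) {
    k <- hits$chrom == region$chrom & hits$pos >= region$start &
      hits$pos <= region$end
    if (filter$strand != "both") k <- k & hits$strand == filter$strand
    if (!is.null(filter$minweight)) k <- k & hits$weight >= filter$minweight
    hits[k, , drop = FALSE]
  }
  list(
    select = sel,
    count = function(region, filter = hit_filter()) nrow(sel(region, filter)),
    sum = function(region, filter = hit_filter()) sum(sel(region, filter)$weight),
    hist = function(region, binwidth, mode = "count", filter = hit_filter()) {
      s <- sel(region, filter)
      if (!nrow(s)) return(data.frame(binstart = integer(), value = numeric()))
      bin <- region$start + binwidth * ((s$pos - region$start) %/% binwidth)
      v <- tapply(if (mode == "count") rep(1, nrow(s)) else s$weight, bin, sum)
      data.frame(binstart = as.integer(names(v)), value = as.numeric(v))
    })
}

#' Generate read pairs with ground truth
#'
#' Pairs are laid out as a forward left end and a reverse right end
#' separated by a 5'-to-5' insert drawn from \code{spec$insert}; a
#' fraction of pairs is interchromosomal when \code{nchrom > 1} is
#' combined with \code{insert = NULL} semantics (here: mates stay on one
#' chromosome; interchromosomal fixtures are built directly in tests).
#'
#' @param spec a [gen_spec()] with \code{paired = TRUE}.
#' @return list with \code{pairs} (a [paired_hits()] data.frame, anchor =
#'   left end) and \code{reads} (pair count).
#' @export
gen_pairs <- function(spec) {
  stopifnot(inherits(spec, "readstore_genspec"), spec$paired)
  p <- with_gen_seed(spec$seed, {
    if (spec$n == 0L) paired_hits() else {
      n <- spec$n
      chrom <- sample.int(spec$nchrom, n, replace = TRUE)
      lo <- max(spec$posrange[1], spec$readlen)
      hi <- spec$posrange[2] - max(spec$insert)
      leftpos <- sample(lo:hi, n, replace = TRUE)
      ins <- sample(spec$insert[1]:spec$insert[2], n, replace = TRUE)
      paired_hits(chrom = chrom, pos = leftpos, strand = "+",
                  length = spec$readlen, matechrom = chrom,
                  matepos = leftpos + ins, matestrand = "-",
                  matelength = spec$readlen, weight = 1.0)
    }
  })
  if (nrow(p)) attr(p, "read") <- sprintf("p%06d", seq_len(spec$n))
  list(pairs = p, reads = spec$n)
}

sam_chrom_name <- function(id) sprintf("chr%d", id)

#' Write a SAM fixture whose import reproduces the generator's hits
#'
#' Emits minimally valid mapped records: forward hits as POS = pos,
#' reverse hits as POS = pos - length + 1 with the reverse flag, CIGAR
#' \code{<len>M}, and an \code{NH} tag carrying each read's alignment
#' multiplicity. Pairs become two mate records with proper pair flags.
#'
#' @param spec a [gen_spec()].
#' @param path output SAM path.
#' @return \code{path}, invisibly; the generated truth (from
#'   [gen_hits()] / [gen_pairs()]) as attribute \code{"truth"}.
#' @export
gen_sam <- function(spec, path) {
  maxpos <- spec$posrange[2] + max(spec$insert) + spec$readlen
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", sam_chrom_name(seq_len(spec$nchrom)),
                   maxpos))
  seqstr <- strrep("A", spec$readlen)
  qual <- strrep("I", spec$readlen)
  cig <- sprintf("%dM", spec$readlen)
  if (!spec$paired) {
    g <- gen_hits(spec)
    h <- g$hits
    read <- attr(h, "read")
    nh <- if (base::length(read)) as.integer(table(read)[read]) else integer()
    recs <- if (nrow(h)) sprintf(
      "%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
      read, ifelse(h$strand == "-", 16L, 0L), sam_chrom_name(h$chrom),
      ifelse(h$strand == "-", h$pos - h$length + 1L, h$pos),
      cig, seqstr, qual, nh) else character()
    writeLines(c(hdr, recs), path)
    return(invisible(structure(path, truth = g)))
  }
  g <- gen_pairs(spec)
  p <- g$pairs
  read <- attr(p, "read")
  recs <- character()
  if (nrow(p)) {
    sam_pos <- function(pos, strand, len)
      ifelse(strand == "-", pos - len + 1L, pos)
    p1 <- sam_pos(p$pos, p$strand, p$length)
    p2 <- sam_pos(p$matepos, p$matestrand, p$matelength)
    f1 <- 1L + 2L + 64L + ifelse(p$strand == "-", 16L, 0L) +
      ifelse(p$matestrand == "-", 32L, 0L)
    f2 <- 1L + 2L + 128L + ifelse(p$matestrand == "-", 16L, 0L) +
      ifelse(p$strand == "-", 32L, 0L)
    rn2 <- ifelse(p$matechrom == p$chrom, "=", sam_chrom_name(p$matechrom))
    rn1 <- ifelse(p$matechrom == p$chrom, "=", sam_chrom_name(p$chrom))
    tlen <- ifelse(p$matechrom == p$chrom, p2 - p1 + p$matelength, 0L)
    recs <- c(sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t%d\t%s\t%s\tNH:i:1",
                      read, f1, sam_chrom_name(p$chrom), p1, cig, rn2, p2,
                      tlen, seqstr, qual),
              sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t%d\t%s\t%s\tNH:i:1",
                      read, f2, sam_chrom_name(p$matechrom), p2, cig, rn1, p1,
                      -tlen, seqstr, qual))
  }
  writeLines(c(hdr, recs), path)
  invisible(structure(path, truth = g))
}

#' Write a BED fixture for the generator's hits
#'
#' BED intervals are half-open 0-based; a forward hit at pos p with
#' length L becomes \code{[p-1, p-1+L)}, a reverse hit \code{[p-L, p)},
#' with the hit weight in the score column.
#'
#' @inheritParams gen_sam
#' @export
gen_bed <- function(spec, path) {
  g <- gen_hits(spec)
  h <- g$hits
  lines <- if (nrow(h)) {
    start0 <- ifelse(h$strand == "-", h$pos - h$length, h$pos - 1L)
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", sam_chrom_name(h$chrom), start0,
            start0 + h$length, attr(h, "read"),
            format(h$weight, trim = TRUE, digits = 9), h$strand)
  } else character()
  writeLines(lines, path)
  invisible(structure(path, truth = g))
}
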