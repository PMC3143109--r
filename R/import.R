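# Importers: SAM/BAM and BED to stored hits. The aligned length is the
# reference-consuming span of the alignment (so spliced or gapped
# alignments get their genomic footprint); the stored position is the 5'
# end — leftmost aligned base on the forward strand, rightmost on the
# reverse strand. The weight of a read with k alignments is 1/k, taken
# from the NH tag when present and otherwise from a read-name count, so
# every read contributes total mass 1 regardless of multi-mapping.

# Read a SAM (text, converted in a scratch dir) or BAM file into a
# GAlignments with qname, flag and NH.
read_alignments <- function(file, paired = FALSE) {
  is_bam <- grepl("\\.bam$", file, ignore.case = TRUE)
  bam <- if (is_bam) file else {
    tmp <- tempfile(fileext = "")
    Rsamtools::asBam(file, destination = tmp, overwrite = TRUE,
                     indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
}

ga_fields <- function(ga) {
  mc <- S4Vectors::mcols(ga)
  list(qname = mc$qname,
       flag = mc$flag,
       nh = mc$NH,
       chromname = as.character(GenomeInfoDb::seqnames(ga)),
       start = GenomicAlignments::start(ga),
       end = GenomicAlignments::end(ga),
       strand = as.character(GenomicAlignments::strand(ga)))
}

#' Import single-end alignments from SAM/BAM
#'
#' Converts mapped records to hits (5' position, strand,
#' reference-consuming span, weight = 1 / alignment count) and stores
#' them in the alignment directory, assigning integer chromosome ids via
#' the sidecar name map (stable across re-imports). Records whose span
#' exceeds the 15-bit length field (32767 bases) are skipped and
#' counted.
#'
#' @param file path to a SAM or BAM file.
#' @param align alignment directory (created if needed).
#' @return import report: list with \code{read} (mapped records seen),
#'   \code{imported}, and \code{skipped} counts, invisibly.
#' @export
import_sam <- function(file, align) {
  align <- align_open(align)
  ga <- read_alignments(file)
  f <- ga_fields(ga)
  n_seen <- base::length(f$qname)
  if (n_seen == 0L)
    return(invisible(list(read = 0L, imported = 0L, skipped = 0L)))
  # drop secondary-of-pair records; single-end import takes unpaired only
  unpaired <- bitwAnd(f$flag, 1L) == 0L
  span <- f$end - f$start + 1L
  ok <- unpaired & span <= MAX_LEN
  skipped_long <- sum(unpaired & span > MAX_LEN)
  if (skipped_long)
    warning(skipped_long, " record(s) skipped: span > ", MAX_LEN)
  qn <- f$qname[ok]
  k <- f$nh[ok]
  if (is.null(k) || all(is.na(k))) k <- rep(NA_integer_, sum(ok))
  name_count <- table(qn)
  k <- ifelse(is.na(k), as.integer(name_count[qn]), k)
  pos <- ifelse(f$strand[ok] == "-", f$end[ok], f$start[ok])
  ids <- chrom_map_ids(align, f$chromname[ok])
  hits <- single_hits(chrom = ids, pos = pos,
                      strand = ifelse(f$strand[ok] == "-", "-", "+"),
                      length = span[ok], weight = 1 / k)
  store_single(align, hits)
  invisible(list(read = n_seen, imported = nrow(hits),
                 skipped = n_seen - nrow(hits)))
}

#' Import paired-end alignments from SAM/BAM
#'
#' Mates are joined by read name; the "left" end of a pair is the one
#' with the smaller (chromosome id, 5' position) key, ties broken by
#' strand (+ first). Each pair is stored twice, keyed by either end (see
#' [store_paired()]). Pair weight is 1 / (number of alignments of the
#' pair). Orphan mates are skipped and tallied.
#'
#' @inheritParams import_sam
#' @return import report list (\code{read} = mapped paired records,
#'   \code{imported} = pairs stored, \code{skipped} = orphan or
#'   over-long records), invisibly.
#' @export
import_sam_paired <- function(file, align) {
  align <- align_open(align)
  ga <- read_alignments(file)
  f <- ga_fields(ga)
  paired <- bitwAnd(f$flag, 1L) != 0L
  first <- paired & bitwAnd(f$flag, 64L) != 0L
  last <- paired & bitwAnd(f$flag, 128L) != 0L
  span <- f$end - f$start + 1L
  usable <- (first | last) & span <= MAX_LEN
  i1 <- which(first & usable); i2 <- which(last & usable)
  m <- match(f$qname[i1], f$qname[i2])
  got <- !is.na(m)
  a <- i1[got]; b <- i2[m[got]]
  n_pairs <- base::length(a)
  orphans <- sum(paired) - 2L * n_pairs
  if (n_pairs == 0L)
    return(invisible(list(read = sum(paired), imported = 0L,
                          skipped = orphans)))
  k <- table(f$qname[a])[f$qname[a]]
  pos_of <- function(i) ifelse(f$strand[i] == "-", f$end[i], f$start[i])
  ids_a <- chrom_map_ids(align, f$chromname[a])
  ids_b <- chrom_map_ids(align, f$chromname[b])
  pairs <- paired_hits(
    chrom = ids_a, pos = pos_of(a), strand = f$strand[a],
    length = span[a],
    matechrom = ids_b, matepos = pos_of(b), matestrand = f$strand[b],
    matelength = span[b], weight = 1 / as.integer(k))
  store_paired(align, pairs)
  invisible(list(read = sum(paired), imported = n_pairs, skipped = orphans))
}

#' Import a BED file as single-end hits
#'
#' BED intervals are half-open 0-based: \code{[chromStart, chromEnd)}
#' of length \code{chromEnd - chromStart}. The 5' position is
#' \code{chromStart + 1} on the forward strand and \code{chromEnd} on
#' the reverse; a missing strand is treated as forward. The score
#' column, when a finite positive number, becomes the hit weight
#' (otherwise 1).
#'
#' @param file path to a BED3+ file.
#' @param align alignment directory.
#' @return import report list, invisibly.
#' @export
import_bed <- function(file, align) {
  align <- align_open(align)
  gr <- rtracklayer::import(file, format = "BED")
  n <- base::length(gr)
  if (n == 0L)
    return(invisible(list(read = 0L, imported = 0L, skipped = 0L)))
  st <- as.character(GenomicAlignments::strand(gr))
  st[st == "*"] <- "+"
  len <- GenomicAlignments::width(gr)
  keep <- len >= 1L & len <= MAX_LEN
  gr <- gr[keep]; st <- st[keep]; len <- len[keep]
  sc <- S4Vectors::mcols(gr)$score
  w <- if (is.null(sc)) rep(1.0, base::length(gr)) else as.double(sc)
  w[!is.finite(w) | w <= 0] <- 1.0
  pos <- ifelse(st == "-", GenomicAlignments::end(gr),
                GenomicAlignments::start(gr))
  ids <- chrom_map_ids(align, as.character(GenomeInfoDb::seqnames(gr)))
  hits <- single_hits(chrom = ids, pos = pos, strand = st, length = len,
                      weight = w)
  store_single(align, hits)
  invisible(list(read = n, imported = nrow(hits), skipped = n - nrow(hits)))
}
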