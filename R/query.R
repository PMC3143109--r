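# Indexed interval queries over the column store. A region query seeks
# via the block index to the block containing the region start, decodes
# the position column forward only until the block holding the region
# end, then slices the matching contiguous record range out of the other
# columns. Decoded work is therefore O(log n) seek + m + at most two
# partial blocks, never a function of total store size n.
#
# Selection is by the stored 5' position (the sort/index key), not span
# overlap: a minus-strand hit whose span reaches into a region but whose
# 5' coordinate lies outside it is not returned.

#' Locate the scan start for a position
#'
#' Binary-searches a block index for the block whose first position is
#' the greatest one \code{<=} the query position (record offset 0 when
#' the position precedes every entry). No record at or after the query
#' position lies before the returned offset.
#'
#' @param idx a \code{readstore_index} from [build_index()].
#' @param position query coordinate.
#' @return 0-based record offset at which a forward scan may begin.
#' @export
locate <- function(idx, position) {
  if (!base::length(idx$offset)) return(0L)
  # blocks with firstpos strictly below the query position: a block whose
  # first position equals the query may be preceded by equal positions
  # spilling over from the previous block, so seek one block earlier
  k <- findInterval(position - 1, idx$firstpos)
  if (k == 0L) 0L else idx$offset[k]
}

# Core region scan of one partition. Returns the contiguous 0-based
# record range [lo, hi) matching start <= pos <= end, plus the decoded
# positions of that range and the count of records decoded to find it.
scan_range <- function(align, chrom, partition, start, end) {
  n <- partition_count(align, chrom, partition)
  if (n == 0L)
    return(list(lo = 0L, hi = 0L, pos = integer(), decoded = 0L))
  idx <- cached_index(col_path(align, chrom, partition, "index"))
  s <- locate(idx, start)
  # first block whose first position exceeds the region end: nothing at
  # or beyond it can match, so the decode window stops there
  k <- findInterval(end, idx$firstpos)
  stop_at <- if (k >= base::length(idx$offset)) n else idx$offset[k + 1L]
  if (stop_at <= s)
    return(list(lo = s, hi = s, pos = integer(), decoded = 0L))
  pos <- read_col(align, chrom, partition, "positions", s, stop_at, POS_BYTES)
  lo <- s + findInterval(start - 1L, pos)            # records with pos < start
  hi <- s + findInterval(end, pos)                   # records with pos <= end
  lo <- as.integer(lo); hi <- as.integer(hi)
  list(lo = lo, hi = hi,
       pos = if (hi > lo) pos[(lo - s + 1L):(hi - s)] else integer(),
       decoded = base::length(pos))
}

apply_filter_mask <- function(align, chrom, partition, lo, hi, filter) {
  m <- hi - lo
  keep <- rep(TRUE, m)
  strand <- NULL; length_ <- NULL; weight <- NULL
  if (filter$strand != "both" || !is.null(filter$minweight) ||
      isTRUE(attr(filter, "need_all"))) {
    at <- read_col(align, chrom, partition, "attrs", lo, hi, ATTR_BYTES,
                   signed = FALSE)
    sl <- unpack_strand_length(at)
    strand <- sl$strand; length_ <- sl$length
    if (filter$strand != "both") keep <- keep & (strand == filter$strand)
  }
  if (!is.null(filter$minweight) || isTRUE(attr(filter, "need_all"))) {
    weight <- read_col(align, chrom, partition, "weights", lo, hi,
                       WEIGHT_BYTES, what = "double")
    if (!is.null(filter$minweight))
      keep <- keep & (weight >= filter$minweight)
  }
  list(keep = keep, strand = strand, length = length_, weight = weight)
}

#' Retrieve hits in a region
#'
#' Returns exactly the stored hits whose 5' position lies within
#' \code{[region$start, region$end]} (inclusive) and which pass the
#' filter, in position order. The endedness of the filter selects the
#' single-end, left-keyed, or right-keyed partition; for paired
#' partitions matching is on the keyed side's position. The projection
#' lets callers fetch only positions or only weights, reading a single
#' column file.
#'
#' An unknown chromosome yields an empty result, not an error: a
#' chromosome with no files simply has no mapped reads.
#'
#' The returned object carries a \code{records_decoded} attribute
#' counting position records decoded to answer the query; for an
#' unfiltered query this never exceeds the result size plus two index
#' blocks (2048 records), the practical form of the O(log n + m) query
#' contract.
#'
#' @param align alignment directory.
#' @param region a [region()], or \code{NULL} for the whole alignment.
#' @param filter a [hit_filter()].
#' @param projection \code{"full"}, \code{"positions"} or \code{"weights"}.
#' @return hits data.frame (projection \code{"full"}), or a bare integer /
#'   double vector for the narrow projections.
#' @export
get_hits <- function(align, region = NULL, filter = hit_filter(),
                     projection = c("full", "positions", "weights")) {
  projection <- match.arg(projection)
  part <- partition_of(filter$endedness)
  paired <- part != "single"
  if (is.null(region)) {
    out <- lapply(store_chroms(align), function(ch)
      get_hits(align, region(ch, 1L, MAX_POS), filter, projection))
    dec <- sum(vapply(out, function(x) attr(x, "records_decoded") %||% 0L, 0L))
    res <- if (projection == "full") do.call(rbind, c(list(empty_hits(paired)), out))
           else do.call(c, c(list(if (projection == "positions") integer() else double()), out))
    attr(res, "records_decoded") <- dec
    return(res)
  }
  sc <- scan_range(align, region$chrom, part, region$start, region$end)
  fl <- apply_filter_mask(align, region$chrom, part, sc$lo, sc$hi,
                          structure(filter, need_all = projection == "full"))
  keep <- fl$keep
  res <- if (projection == "positions") {
    sc$pos[keep]
  } else if (projection == "weights") {
    w <- fl$weight %||% read_col(align, region$chrom, part, "weights",
                                 sc$lo, sc$hi, WEIGHT_BYTES, what = "double")
    w[keep]
  } else if (!paired) {
    single_hits(chrom = region$chrom, pos = sc$pos[keep],
                strand = fl$strand[keep], length = fl$length[keep],
                weight = fl$weight[keep])
  } else {
    mc <- read_col(align, region$chrom, part, "matechrom", sc$lo, sc$hi, POS_BYTES)
    mp <- read_col(align, region$chrom, part, "matepos", sc$lo, sc$hi, POS_BYTES)
    ma <- read_col(align, region$chrom, part, "mateattrs", sc$lo, sc$hi,
                   ATTR_BYTES, signed = FALSE)
    msl <- unpack_strand_length(if (base::length(ma)) ma else 1L)
    paired_hits(chrom = region$chrom, pos = sc$pos[keep],
                strand = fl$strand[keep], length = fl$length[keep],
                matechrom = mc[keep], matepos = mp[keep],
                matestrand = if (base::length(ma)) msl$strand[keep] else character(),
                matelength = if (base::length(ma)) msl$length[keep] else integer(),
                weight = fl$weight[keep])
  }
  attr(res, "records_decoded") <- sc$decoded
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count hits in a region or alignment
#'
#' Equivalent to the size of the [get_hits()] result without
#' materializing hit rows. With no region and no filter the count comes
#' straight from the column file sizes.
#'
#' @inheritParams get_hits
#' @return integer count.
#' @export
count_hits <- function(align, region = NULL, filter = hit_filter()) {
  part <- partition_of(filter$endedness)
  unfiltered <- filter$strand == "both" && is.null(filter$minweight)
  if (is.null(region)) {
    if (unfiltered)
      return(sum(vapply(store_chroms(align), partition_count, 0L,
                        align = align, partition = part)))
    return(sum(vapply(store_chroms(align), function(ch)
      count_hits(align, region(ch, 1L, MAX_POS), filter), 0L)))
  }
  sc <- scan_range(align, region$chrom, part, region$start, region$end)
  if (unfiltered) return(sc$hi - sc$lo)
  fl <- apply_filter_mask(align, region$chrom, part, sc$lo, sc$hi, filter)
  sum(fl$keep)
}

#' Sum hit weights in a region or alignment
#'
#' Weights are stored as 32-bit floats but accumulated in double
#' precision.
#'
#' @inheritParams get_hits
#' @return double; 0 for an empty selection.
#' @export
sum_weights <- function(align, region = NULL, filter = hit_filter()) {
  part <- partition_of(filter$endedness)
  if (is.null(region))
    return(sum(vapply(store_chroms(align), function(ch)
      sum_weights(align, region(ch, 1L, MAX_POS), filter), 0.0)))
  sc <- scan_range(align, region$chrom, part, region$start, region$end)
  fl <- apply_filter_mask(align, region$chrom, part, sc$lo, sc$hi, filter)
  w <- fl$weight %||% read_col(align, region$chrom, part, "weights",
                               sc$lo, sc$hi, WEIGHT_BYTES, what = "double")
  sum(w[fl$keep])
}

#' Histogram of hit counts or weight sums across a region
#'
#' Bins anchor at the region start: a hit at position p falls in the bin
#' starting at \code{start + binwidth * floor((p - start) / binwidth)}.
#' Only non-empty bins are returned, so a count histogram's bin values
#' sum exactly to [count_hits()] over the same region and filter.
#' Server-side histograms condense many hits into few bins, which is the
#' point: far less data crosses the network than per-read results.
#'
#' @inheritParams get_hits
#' @param binwidth positive integer bin width in bases.
#' @param mode \code{"count"} or \code{"weight"}.
#' @return data.frame with integer \code{binstart} (1-based bin start
#'   coordinates) and numeric \code{value}, sorted by binstart.
#' @export
histogram_query <- function(align, region, binwidth,
                            mode = c("count", "weight"),
                            filter = hit_filter()) {
  mode <- match.arg(mode)
  binwidth <- as.integer(binwidth)
  if (is.na(binwidth) || binwidth < 1L) stop("binwidth must be >= 1")
  part <- partition_of(filter$endedness)
  sc <- scan_range(align, region$chrom, part, region$start, region$end)
  fl <- apply_filter_mask(align, region$chrom, part, sc$lo, sc$hi,
                          structure(filter, need_all = mode == "weight"))
  p <- sc$pos[fl$keep]
  if (!base::length(p))
    return(data.frame(binstart = integer(), value = numeric()))
  bin <- region$start + binwidth * ((p - region$start) %/% binwidth)
  if (mode == "count") {
    tb <- table(bin)
    data.frame(binstart = as.integer(names(tb)), value = as.numeric(tb))
  } else {
    w <- fl$weight[fl$keep]
    agg <- tapply(w, bin, sum)
    data.frame(binstart = as.integer(names(agg)), value = as.numeric(agg))
  }
}

#' List chromosomes with stored reads
#'
#' @param align alignment directory (must exist).
#' @return [alignment_meta()] data.frame: exactly the chromosomes with at
#'   least one stored record in either partition.
#' @export
list_chromosomes <- function(align) {
  if (!dir.exists(align)) stop("alignment not found: ", align)
  alignment_meta(align)
}
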