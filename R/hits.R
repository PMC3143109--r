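# Domain types: hits, regions, filters. All coordinates are 1-based
# inclusive; for minus-strand hits `pos` is the 5' end, i.e. the
# highest-coordinate aligned base, and the covered interval is
# [pos - length + 1, pos].

MAX_POS <- 2147483647L      # 32-bit signed position column
MAX_LEN <- 32767L           # 15-bit length field
STRAND_BIT <- 32768L        # bit 15 of the packed strand/length word

#' Pack strand and aligned length into a 16-bit word
#'
#' Hits store their strand and aligned length together in one 16-bit
#' unsigned word: bit 15 carries the strand (0 = \code{+}, 1 = \code{-})
#' and bits 0-14 carry the length in bases. This is the on-disk encoding
#' of the attrs column.
#'
#' @param strand character vector of \code{"+"} / \code{"-"}.
#' @param length integer vector of aligned lengths, 1..32767.
#' @return integer vector of packed 16-bit words (0..65535).
#' @seealso [unpack_strand_length()]
#' @examples
#' pack_strand_length("+", 36)  # 36
#' pack_strand_length("-", 36)  # 32804
#' @export
pack_strand_length <- function(strand, length) {
  length <- as.integer(length)
  if (any(is.na(length)) || any(length < 1L) || any(length > MAX_LEN))
    stop("length out of range 1..", MAX_LEN)
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) stop("strand must be '+' or '-'")
  ifelse(strand == "-", STRAND_BIT + length, length)
}

#' Unpack a 16-bit strand/length word
#'
#' Exact inverse of [pack_strand_length()]. A word whose low 15 bits are
#' zero encodes length 0, which no valid hit can have; it is rejected as
#' a corrupt record.
#'
#' @param word integer vector of packed words (0..65535).
#' @return list with character vector \code{strand} and integer vector
#'   \code{length}.
#' @export
unpack_strand_length <- function(word) {
  word <- as.integer(word)
  if (any(is.na(word)) || any(word < 0L) || any(word > 65535L))
    stop("packed word out of 16-bit range")
  len <- word %% STRAND_BIT
  if (any(len == 0L)) stop("corrupt record: encoded length 0")
  list(strand = ifelse(word >= STRAND_BIT, "-", "+"), length = len)
}

#' Construct a validated set of single-end hits
#'
#' A hit is one mapped occurrence of a read: an integer chromosome id, the
#' 1-based 5' coordinate, strand, aligned span length, and a non-negative
#' weight (typically 1/k for a read with k alignments so each read
#' contributes total mass 1).
#'
#' @param chrom non-negative integer chromosome ids.
#' @param pos 1-based 5' coordinates (32-bit signed range).
#' @param strand \code{"+"} or \code{"-"} per hit.
#' @param length aligned span in bases, 1..32767.
#' @param weight non-negative finite weights (stored as 32-bit floats).
#' @return data.frame of class \code{readstore_hits} with one row per hit.
#' @export
single_hits <- function(chrom = integer(), pos = integer(), strand = character(),
                        length = integer(), weight = numeric()) {
  n <- base::length(pos)
  chrom <- rep_len(as.integer(chrom), n)
  pos <- as.integer(pos)
  strand <- rep_len(as.character(strand), n)
  length <- rep_len(as.integer(length), n)
  weight <- rep_len(as.double(weight), n)
  validate_hit_fields(chrom, pos, strand, length, weight)
  h <- data.frame(chrom = chrom, pos = pos, strand = strand,
                  length = length, weight = weight,
                  stringsAsFactors = FALSE)
  class(h) <- c("readstore_hits", "data.frame")
  h
}

#' Construct a validated set of read pairs
#'
#' A pair carries all single-hit fields for the anchor side plus the
#' mate's chromosome, 5' position, strand and length; the weight applies
#' to the pair as a whole.
#'
#' @inheritParams single_hits
#' @param matechrom,matepos,matestrand,matelength the mate side's fields,
#'   with the same range constraints as the anchor side.
#' @return data.frame of class \code{readstore_pairs}.
#' @export
paired_hits <- function(chrom = integer(), pos = integer(), strand = character(),
                        length = integer(), matechrom = integer(),
                        matepos = integer(), matestrand = character(),
                        matelength = integer(), weight = numeric()) {
  n <- base::length(pos)
  chrom <- rep_len(as.integer(chrom), n); pos <- as.integer(pos)
  strand <- rep_len(as.character(strand), n)
  length <- rep_len(as.integer(length), n)
  matechrom <- rep_len(as.integer(matechrom), n)
  matepos <- as.integer(rep_len(matepos, n))
  matestrand <- rep_len(as.character(matestrand), n)
  matelength <- rep_len(as.integer(matelength), n)
  weight <- rep_len(as.double(weight), n)
  validate_hit_fields(chrom, pos, strand, length, weight)
  validate_hit_fields(matechrom, matepos, matestrand, matelength, weight)
  p <- data.frame(chrom = chrom, pos = pos, strand = strand, length = length,
                  matechrom = matechrom, matepos = matepos,
                  matestrand = matestrand, matelength = matelength,
                  weight = weight, stringsAsFactors = FALSE)
  class(p) <- c("readstore_pairs", "data.frame")
  p
}

validate_hit_fields <- function(chrom, pos, strand, length, weight) {
  if (any(is.na(chrom)) || any(chrom < 0L))
    stop("chrom must be a non-negative integer")
  if (any(is.na(pos)) || any(pos < 1L))
    stop("pos must be in 1..2^31-1")
  if (any(!(strand %in% c("+", "-"))))
    stop("strand must be '+' or '-'")
  if (any(is.na(length)) || any(length < 1L) || any(length > MAX_LEN))
    stop("length out of range 1..", MAX_LEN)
  if (any(!is.finite(weight)) || any(weight < 0))
    stop("weight must be finite and >= 0")
  invisible(TRUE)
}

#' Define a genomic query region
#'
#' @param chrom integer chromosome id (or a name resolvable by the caller).
#' @param start,end 1-based inclusive bounds, \code{start <= end}.
#' @return list of class \code{readstore_region}.
#' @export
region <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("invalid region: need 1 <= start <= end")
  structure(list(chrom = as.integer(chrom), start = start, end = end),
            class = "readstore_region")
}

#' Define a hit filter
#'
#' Queries may be filtered by strand, by a minimum weight (inclusive:
#' hits are kept when \code{weight >= minweight}), and by endedness,
#' which selects the single-end partition or the left-/right-keyed
#' paired partition.
#'
#' @param strand \code{"+"}, \code{"-"}, or \code{"both"}.
#' @param minweight optional non-negative weight threshold.
#' @param endedness \code{"single"}, \code{"paired-left"} or
#'   \code{"paired-right"}.
#' @return list of class \code{readstore_filter}.
#' @export
hit_filter <- function(strand = "both", minweight = NULL,
                       endedness = "single") {
  strand <- match.arg(strand, c("both", "+", "-"))
  endedness <- match.arg(endedness, c("single", "paired-left", "paired-right"))
  if (!is.null(minweight)) {
    minweight <- as.double(minweight)
    if (!is.finite(minweight) || minweight < 0)
      stop("minweight must be finite and >= 0")
  }
  structure(list(strand = strand, minweight = minweight,
                 endedness = endedness), class = "readstore_filter")
}

# Map an endedness filter value to the on-disk partition name.
partition_of <- function(endedness) {
  switch(endedness,
         "single" = "single",
         "paired-left" = "pairedL",
         "paired-right" = "pairedR",
         stop("unknown endedness: ", endedness))
}

empty_hits <- function(paired = FALSE) {
  if (paired) paired_hits() else single_hits()
}
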