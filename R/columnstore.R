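# On-disk column store. One directory per alignment; per chromosome and
# endedness partition a set of parallel little-endian binary column
# files plus a sparse block index:
#
#   <align>/<chrom>.<single|pairedL|pairedR>.positions   int32, 4 B/record
#   <align>/<chrom>.<part>.attrs                         uint16, 2 B/record
#   <align>/<chrom>.<part>.weights                       float32, 4 B/record
#   <align>/<chrom>.pairedL|pairedR.matechrom            int32, 4 B/record
#   <align>/<chrom>.pairedL|pairedR.matepos              int32, 4 B/record
#   <align>/<chrom>.pairedL|pairedR.mateattrs            uint16, 2 B/record
#   <align>/<chrom>.<part>.index                         8 B/entry
#
# Records are sorted by position; the index holds one (first-position,
# record-offset) entry per BLOCK_SIZE records. Full layout in FORMAT.md.

BLOCK_SIZE <- 1024L   # records per index block = 4 kb of position column
INDEX_ENTRY_BYTES <- 8L
POS_BYTES <- 4L
ATTR_BYTES <- 2L
WEIGHT_BYTES <- 4L

col_path <- function(align, chrom, partition, col) {
  file.path(align, sprintf("%d.%s.%s", as.integer(chrom), partition, col))
}

#' Create (or open) an alignment directory
#'
#' An alignment is a named collection describing where one read set maps
#' to one reference genome; it is the unit of storage and query, held as
#' one directory of per-chromosome column files.
#'
#' @param dir path of the alignment directory; created if absent.
#' @return the normalized path, invisibly usable as the `align` argument
#'   of the store and query functions.
#' @export
align_open <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  normalizePath(dir)
}

# Record count of one partition, from the positions file size.
partition_count <- function(align, chrom, partition) {
  f <- col_path(align, chrom, partition, "positions")
  if (!file.exists(f)) return(0L)
  sz <- file.size(f)
  if (sz %% POS_BYTES != 0)
    stop("corrupt store: positions file size not a multiple of 4: ", f)
  as.integer(sz / POS_BYTES)
}

# Chromosome ids present in an alignment (>= 1 record in any partition).
store_chroms <- function(align) {
  fs <- list.files(align, pattern = "^[0-9]+\\.(single|pairedL|pairedR)\\.positions$")
  if (!base::length(fs)) return(integer())
  ids <- as.integer(sub("\\..*$", "", fs))
  keep <- file.size(file.path(align, fs)) > 0
  sort(unique(ids[keep]))
}

#' Write single-end hits into an alignment
#'
#' Incoming hits are merged with any records already on disk into a
#' single position-sorted set per chromosome; the column files are
#' rewritten consistently and the block index rebuilt. Writing any
#' permutation of the same hit multiset yields byte-identical files.
#'
#' @param align alignment directory (see [align_open()]).
#' @param hits a [single_hits()] data.frame; may span several chromosomes.
#' @return the alignment path, invisibly.
#' @export
store_single <- function(align, hits) {
  stopifnot(inherits(hits, "readstore_hits"))
  for (ch in unique(hits$chrom))
    write_chrom_single(align, ch, hits[hits$chrom == ch, , drop = FALSE])
  invisible(align)
}

write_chrom_single <- function(align, chrom, hits) {
  old <- read_records(align, chrom, "single", 0L,
                      partition_count(align, chrom, "single"))
  all <- rbind(old[, c("pos", "strand", "length", "weight")],
               hits[, c("pos", "strand", "length", "weight")])
  attrs <- pack_strand_length(all$strand, all$length)
  w32 <- float32_round(all$weight)
  o <- order(all$pos, attrs, w32)   # total order => order-insensitive bytes
  write_columns(align, chrom, "single",
                pos = all$pos[o], attrs = attrs[o], weights = w32[o])
}

#' Write read pairs into an alignment (dual-keyed)
#'
#' Each pair is stored twice: once in the left-keyed partition of the
#' left end's chromosome, sorted by the left end's position, and once in
#' the right-keyed partition of the right end's chromosome, so interval
#' queries can anchor on either end at a small storage cost. The left
#' end is the one with the smaller (chromosome, 5' position) key, ties
#' broken by strand (\code{+} first).
#'
#' @param align alignment directory.
#' @param pairs a [paired_hits()] data.frame (anchor side arbitrary; pairs
#'   are canonicalized internally).
#' @return the alignment path, invisibly.
#' @export
store_paired <- function(align, pairs) {
  stopifnot(inherits(pairs, "readstore_pairs"))
  if (!nrow(pairs)) return(invisible(align))
  anchor_is_left <- with(pairs,
    chrom < matechrom |
    (chrom == matechrom & pos < matepos) |
    (chrom == matechrom & pos == matepos &
       (strand == "+" | strand == matestrand)))
  left <- pairs
  sw <- !anchor_is_left
  left[sw, c("chrom","pos","strand","length",
             "matechrom","matepos","matestrand","matelength")] <-
    pairs[sw, c("matechrom","matepos","matestrand","matelength",
                "chrom","pos","strand","length")]
  right <- left
  right[, c("chrom","pos","strand","length",
            "matechrom","matepos","matestrand","matelength")] <-
    left[, c("matechrom","matepos","matestrand","matelength",
             "chrom","pos","strand","length")]
  for (ch in unique(left$chrom))
    write_chrom_paired(align, ch, "pairedL", left[left$chrom == ch, , drop = FALSE])
  for (ch in unique(right$chrom))
    write_chrom_paired(align, ch, "pairedR", right[right$chrom == ch, , drop = FALSE])
  invisible(align)
}

write_chrom_paired <- function(align, chrom, partition, pairs) {
  old <- read_records(align, chrom, partition, 0L,
                      partition_count(align, chrom, partition))
  cols <- c("pos","strand","length","weight",
            "matechrom","matepos","matestrand","matelength")
  all <- rbind(old[, cols], pairs[, cols])
  attrs <- pack_strand_length(all$strand, all$length)
  mattrs <- pack_strand_length(all$matestrand, all$matelength)
  w32 <- float32_round(all$weight)
  o <- order(all$pos, attrs, w32, all$matechrom, all$matepos, mattrs)
  write_columns(align, chrom, partition,
                pos = all$pos[o], attrs = attrs[o], weights = w32[o],
                matechrom = all$matechrom[o], matepos = all$matepos[o],
                mateattrs = mattrs[o])
}

# Round doubles through 32-bit float storage precision.
float32_round <- function(w) {
  if (!base::length(w)) return(double())
  readBin(writeBin(as.double(w), raw(), size = 4L, endian = "little"),
          "double", n = base::length(w), size = 4L, endian = "little")
}

write_columns <- function(align, chrom, partition, pos, attrs, weights,
                          matechrom = NULL, matepos = NULL, mateattrs = NULL) {
  if (is.unsorted(pos)) stop("internal error: unsorted positions")
  put <- function(col, data, size, what = "integer") {
    f <- col_path(align, chrom, partition, col)
    con <- file(f, "wb")
    on.exit(close(con))
    if (base::length(data))
      writeBin(if (what == "double") as.double(data) else as.integer(data),
               con, size = size, endian = "little")
  }
  put("positions", pos, POS_BYTES)
  put("attrs", attrs, ATTR_BYTES)
  put("weights", weights, WEIGHT_BYTES, what = "double")
  if (!is.null(matechrom)) {
    put("matechrom", matechrom, POS_BYTES)
    put("matepos", matepos, POS_BYTES)
    put("mateattrs", mateattrs, ATTR_BYTES)
  }
  idx <- build_index(pos)
  write_index(col_path(align, chrom, partition, "index"), idx)
  invisible(NULL)
}

#' Build a block index over a sorted position column
#'
#' The index samples the sorted positions every \code{BLOCK_SIZE} (1024)
#' records, recording each block's first position and record offset; it
#' plays the role of a single B-tree block and gives O(log n) entry into
#' the hit list. At 4 bytes per position record and 8 bytes per index
#' entry, a 64 kb index addresses 1024 * 8192 = 8,388,608 records.
#'
#' @param positions sorted non-decreasing integer vector.
#' @return list of class \code{readstore_index} with integer vectors
#'   \code{firstpos} and \code{offset} (0-based record offsets).
#' @export
build_index <- function(positions) {
  if (is.unsorted(positions)) stop("corruption: positions not sorted")
  n <- base::length(positions)
  if (n == 0L)
    return(structure(list(firstpos = integer(), offset = integer()),
                     class = "readstore_index"))
  off <- seq.int(0L, n - 1L, by = BLOCK_SIZE)
  structure(list(firstpos = positions[off + 1L], offset = off),
            class = "readstore_index")
}

write_index <- function(path, idx) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (base::length(idx$offset)) {
    inter <- integer(2L * base::length(idx$offset))
    inter[c(TRUE, FALSE)] <- idx$firstpos
    inter[c(FALSE, TRUE)] <- idx$offset
    writeBin(inter, con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_index <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(structure(list(firstpos = integer(), offset = integer()),
                     class = "readstore_index"))
  sz <- file.size(path)
  if (sz %% INDEX_ENTRY_BYTES != 0)
    stop("corrupt store: index file size not a multiple of 8: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = sz / 4L, size = 4L, endian = "little")
  structure(list(firstpos = v[c(TRUE, FALSE)], offset = v[c(FALSE, TRUE)]),
            class = "readstore_index")
}

# Index cache: avoids re-reading index files for repeated queries (the
# server keeps many small index files hot in memory). Invalidated by
# file mtime+size.
.index_cache <- new.env(parent = emptyenv())

cached_index <- function(path) {
  info <- file.info(path)
  key <- path
  stamp <- paste(info$size, as.numeric(info$mtime))
  hit <- .index_cache[[key]]
  if (!is.null(hit) && identical(hit$stamp, stamp)) return(hit$idx)
  idx <- read_index(path)
  .index_cache[[key]] <- list(stamp = stamp, idx = idx)
  idx
}

# Decode records [from, to) (0-based, end-exclusive) of one partition.
read_col <- function(align, chrom, partition, col, from, to,
                     size, what = "integer", signed = TRUE) {
  f <- col_path(align, chrom, partition, col)
  n <- to - from
  if (n == 0L) return(if (what == "double") double() else integer())
  if (!file.exists(f)) stop("missing column file: ", f)
  con <- file(f, "rb")
  on.exit(close(con))
  seek(con, where = from * size)
  out <- readBin(con, what, n = n, size = size, signed = signed,
                 endian = "little")
  if (base::length(out) != n)
    stop("corrupt store: short read from ", f)
  out
}

#' Decode a record range from a partition
#'
#' Reads the parallel column files for 0-based records \code{[from, to)}
#' and decodes them back into hit rows; round-trips with [store_single()]
#' and [store_paired()] (weights at 32-bit float precision).
#'
#' @param align alignment directory.
#' @param chrom integer chromosome id.
#' @param partition \code{"single"}, \code{"pairedL"} or \code{"pairedR"}.
#' @param from,to 0-based record range, end-exclusive; \code{0 <= from <=
#'   to <= N}.
#' @return hits (or pairs) data.frame in stored order.
#' @export
read_records <- function(align, chrom, partition = "single", from, to) {
  n <- partition_count(align, chrom, partition)
  from <- as.integer(from); to <- as.integer(to)
  if (from < 0L || to < from || to > n)
    stop("record range [", from, ",", to, ") outside 0..", n)
  paired <- partition != "single"
  if (to == from) return(empty_hits(paired))
  pos <- read_col(align, chrom, partition, "positions", from, to, POS_BYTES)
  at <- read_col(align, chrom, partition, "attrs", from, to, ATTR_BYTES,
                 signed = FALSE)
  w <- read_col(align, chrom, partition, "weights", from, to, WEIGHT_BYTES,
                what = "double")
  sl <- unpack_strand_length(at)
  if (!paired)
    return(single_hits(chrom = chrom, pos = pos, strand = sl$strand,
                       length = sl$length, weight = w))
  mc <- read_col(align, chrom, partition, "matechrom", from, to, POS_BYTES)
  mp <- read_col(align, chrom, partition, "matepos", from, to, POS_BYTES)
  ma <- read_col(align, chrom, partition, "mateattrs", from, to, ATTR_BYTES,
                 signed = FALSE)
  msl <- unpack_strand_length(ma)
  paired_hits(chrom = chrom, pos = pos, strand = sl$strand, length = sl$length,
              matechrom = mc, matepos = mp, matestrand = msl$strand,
              matelength = msl$length, weight = w)
}

#' Delete a partition of an alignment
#'
#' Removes the column and index files of the single-end or paired-end
#' partition, per chromosome or for the whole alignment; the other
#' partition is untouched. Idempotent: deleting an already-absent
#' partition is a no-op.
#'
#' @param align alignment directory (must exist).
#' @param endedness \code{"single"} or \code{"paired"} (paired removes
#'   both the left- and right-keyed partitions).
#' @param chrom optional integer id restricting the delete to one
#'   chromosome.
#' @export
delete_hits <- function(align, endedness = c("single", "paired"),
                        chrom = NULL) {
  endedness <- match.arg(endedness)
  if (!dir.exists(align)) stop("alignment not found: ", align)
  parts <- if (endedness == "single") "single" else c("pairedL", "pairedR")
  chroms <- if (is.null(chrom)) store_chroms(align) else as.integer(chrom)
  cols <- c("positions", "attrs", "weights", "matechrom", "matepos",
            "mateattrs", "index")
  for (ch in chroms)
    for (p in parts)
      for (col in cols) {
        f <- col_path(align, ch, p, col)
        if (file.exists(f)) file.remove(f)
      }
  invisible(NULL)
}

#' Summarize an alignment's contents
#'
#' @param align alignment directory.
#' @return data.frame with one row per chromosome: integer \code{chrom},
#'   name (from the sidecar chromosome map, if present), and single-end
#'   and paired-end record counts as stored on disk.
#' @export
alignment_meta <- function(align) {
  if (!dir.exists(align)) stop("alignment not found: ", align)
  chroms <- store_chroms(align)
  cmap <- chrom_map_read(align)
  name <- if (nrow(cmap)) cmap$name[match(chroms, cmap$id)] else
    rep(NA_character_, base::length(chroms))
  data.frame(
    chrom = chroms,
    name = ifelse(is.na(name), as.character(chroms), name),
    single = vapply(chroms, partition_count, 0L, align = align,
                    partition = "single"),
    paired = vapply(chroms, partition_count, 0L, align = align,
                    partition = "pairedL"),
    stringsAsFactors = FALSE)
}

#' Verify store integrity
#'
#' Scans every partition of an alignment and checks the format
#' invariants: parallel column files have consistent sizes (4 + 2 + 4
#' bytes per single-end record plus 4 + 4 + 2 mate bytes per paired
#' record), positions are sorted non-decreasing, and the block index has
#' ceil(N / 1024) entries each pointing at the position actually stored
#' at its record offset.
#'
#' @param align alignment directory.
#' @return character vector of problems found (empty if the store is
#'   intact).
#' @export
verify_alignment <- function(align) {
  probs <- character()
  say <- function(...) probs <<- c(probs, paste0(...))
  for (ch in store_chroms(align)) {
    for (part in c("single", "pairedL", "pairedR")) {
      pf <- col_path(align, ch, part, "positions")
      if (!file.exists(pf)) next
      n <- file.size(pf) / POS_BYTES
      if (n != floor(n)) { say(pf, ": size not multiple of 4"); next }
      expect <- c(attrs = ATTR_BYTES, weights = WEIGHT_BYTES)
      if (part != "single")
        expect <- c(expect, matechrom = POS_BYTES, matepos = POS_BYTES,
                    mateattrs = ATTR_BYTES)
      for (col in names(expect)) {
        f <- col_path(align, ch, part, col)
        if (!file.exists(f)) say(f, ": missing column file")
        else if (file.size(f) != n * expect[[col]])
          say(f, ": size ", file.size(f), " != ", n * expect[[col]])
      }
      pos <- read_col(align, ch, part, "positions", 0L, as.integer(n),
                      POS_BYTES)
      if (is.unsorted(pos)) say(pf, ": positions not sorted")
      idxf <- col_path(align, ch, part, "index")
      if (!file.exists(idxf)) { say(idxf, ": missing index"); next }
      idx <- read_index(idxf)
      want <- as.integer(ceiling(n / BLOCK_SIZE))
      if (base::length(idx$offset) != want)
        say(idxf, ": ", base::length(idx$offset), " entries, expected ", want)
      else if (want > 0 &&
               (!identical(idx$offset, seq.int(0L, as.integer(n) - 1L,
                                               by = BLOCK_SIZE)) ||
                !identical(idx$firstpos, pos[idx$offset + 1L])))
        say(idxf, ": index entries inconsistent with positions")
    }
  }
  probs
}

# ---- chromosome name <-> integer id sidecar -------------------------------

chrom_map_path <- function(align) file.path(align, "chrommap.tsv")

#' Read an alignment's chromosome name map
#'
#' Chromosomes are stored as integers for compactness; the sidecar file
#' \code{chrommap.tsv} (two columns: name, id) records the
#' name-to-integer assignment so names like \code{chrX} survive
#' round-trips. The map is bijective and stable across re-imports.
#'
#' @param align alignment directory.
#' @return data.frame with character \code{name} and integer \code{id}.
#' @export
chrom_map_read <- function(align) {
  f <- chrom_map_path(align)
  if (!file.exists(f))
    return(data.frame(name = character(), id = integer(),
                      stringsAsFactors = FALSE))
  m <- utils::read.table(f, sep = "\t", header = FALSE,
                         col.names = c("name", "id"),
                         colClasses = c("character", "integer"),
                         quote = "", comment.char = "")
  m
}

# Resolve (creating if needed) integer ids for chromosome names.
chrom_map_ids <- function(align, names, create = TRUE) {
  m <- chrom_map_read(align)
  ids <- m$id[match(names, m$name)]
  if (any(is.na(ids)) && create) {
    new <- unique(names[is.na(ids)])
    next_id <- if (nrow(m)) max(m$id) + 1L else 1L
    add <- data.frame(name = new, id = seq.int(next_id, by = 1L,
                                               length.out = base::length(new)),
                      stringsAsFactors = FALSE)
    m <- rbind(m, add)
    utils::write.table(m, chrom_map_path(align), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    ids <- m$id[match(names, m$name)]
  }
  ids
}

# Resolve a chromosome given by name or raw integer id.
resolve_chrom <- function(align, chrom) {
  if (is.numeric(chrom)) return(as.integer(chrom))
  chrom <- as.character(chrom)
  suppressWarnings(num <- as.integer(chrom))
  m <- chrom_map_read(align)
  hit <- m$id[match(chrom, m$name)]
  if (!is.na(hit)) return(hit)
  if (!is.na(num)) return(num)
  stop("unknown chromosome: ", chrom)
}
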