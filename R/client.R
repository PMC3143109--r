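# Client library: thin typed wrappers, one request and one parsed
# response per call, no client-side caching (the server's index cache is
# the performance feature; the client stays correctness-only).

#' Connect to a readstore server
#'
#' @param host server host; default from environment variable
#'   \code{READSTORE_HOST}, else \code{"localhost"}.
#' @param port server TCP port; default from \code{READSTORE_PORT}.
#' @param timeout response timeout in seconds; operations on a dead
#'   server fail after this rather than hanging.
#' @return connection handle of class \code{readstore_connection}.
#' @export
readdb_connect <- function(host = NULL, port = NULL, timeout = 30) {
  host <- host %||% Sys.getenv("READSTORE_HOST", "localhost")
  port <- as.integer(port %||% Sys.getenv("READSTORE_PORT", "52734"))
  sock <- socketConnection(host, port, blocking = TRUE, open = "r+b",
                           timeout = timeout)
  structure(list(sock = sock, host = host, port = port),
            class = "readstore_connection")
}

#' Close a client connection
#' @param con a [readdb_connect()] handle.
#' @export
readdb_disconnect <- function(con) {
  close(con$sock)
  invisible(NULL)
}

check_open <- function(con) {
  if (!inherits(con, "readstore_connection") || !isOpen(con$sock))
    stop("connection is closed")
}

# Send one request (+ payload lines), read "OK n" + n lines or raise a
# typed remote error carrying the server's code and message.
rdb_request <- function(con, line, payload = character()) {
  check_open(con)
  writeLines(c(line, payload), con$sock, sep = "\n")
  flush(con$sock)
  status <- readLines(con$sock, n = 1L, warn = FALSE)
  if (!base::length(status)) stop("connection closed by server")
  if (startsWith(status, "ERROR ")) {
    parts <- strsplit(status, " ")[[1]]
    code <- as.integer(parts[2])
    cond <- structure(
      class = c(if (identical(code, 404L)) "readstore_not_found",
                "readstore_remote_error", "error", "condition"),
      list(message = status, call = NULL, code = code))
    stop(cond)
  }
  if (!startsWith(status, "OK "))
    stop("protocol error: unexpected status line: ", status)
  n <- as.integer(sub("^OK ", "", status))
  if (n == 0L) return(character())
  out <- character()
  while (base::length(out) < n) {
    got <- readLines(con$sock, n = n - base::length(out), warn = FALSE)
    if (!base::length(got)) stop("connection closed mid-response")
    out <- c(out, got)
  }
  out
}

kv <- function(...) {
  args <- list(...)
  args <- args[!vapply(args, is.null, TRUE)]
  if (!base::length(args)) return("")
  paste0(" ", paste(names(args), unlist(lapply(args, as.character)),
                    sep = "=", collapse = " "))
}

filter_kv <- function(filter) {
  list(strand = if (filter$strand != "both") filter$strand,
       minweight = filter$minweight,
       endedness = if (filter$endedness != "single") filter$endedness)
}

region_kv <- function(region) {
  if (is.null(region)) list() else
    list(chrom = region$chrom, start = region$start, end = region$end)
}

#' Store single-end hits through the server
#'
#' @param con a [readdb_connect()] handle.
#' @param align alignment id on the server.
#' @param hits a [single_hits()] data.frame (one chromosome at a time is
#'   sent per request).
#' @export
rdb_store_single <- function(con, align, hits) {
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    payload <- sprintf("%d\t%s\t%d\t%s", h$pos, h$strand, h$length,
                       format(h$weight, digits = 9))
    rdb_request(con, paste0("STORE",
                            kv(align = align, chrom = ch, count = nrow(h))),
                payload)
  }
  invisible(NULL)
}

#' Store read pairs through the server
#' @inheritParams rdb_store_single
#' @param pairs a [paired_hits()] data.frame.
#' @export
rdb_store_paired <- function(con, align, pairs) {
  payload <- sprintf("%d\t%d\t%s\t%d\t%d\t%d\t%s\t%d\t%s",
                     pairs$chrom, pairs$pos, pairs$strand, pairs$length,
                     pairs$matechrom, pairs$matepos, pairs$matestrand,
                     pairs$matelength, format(pairs$weight, digits = 9))
  rdb_request(con, paste0("STOREPAIRED", kv(align = align,
                                            count = nrow(pairs))), payload)
  invisible(NULL)
}

#' Delete a partition of a server-side alignment
#' @inheritParams rdb_store_single
#' @param endedness \code{"single"} or \code{"paired"}.
#' @param chrom optional chromosome restriction.
#' @export
rdb_delete <- function(con, align, endedness = "single", chrom = NULL) {
  rdb_request(con, paste0("DELETE", kv(align = align, endedness = endedness,
                                       chrom = chrom)))
  invisible(NULL)
}

#' List chromosomes of a server-side alignment
#' @inheritParams rdb_store_single
#' @return data.frame: chrom id, name, single and paired record counts.
#' @export
rdb_chroms <- function(con, align) {
  lines <- rdb_request(con, paste0("CHROMS", kv(align = align)))
  if (!base::length(lines))
    return(data.frame(chrom = integer(), name = character(),
                      single = integer(), paired = integer(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(chrom = as.integer(m[, 1]), name = m[, 2],
             single = as.integer(m[, 3]), paired = as.integer(m[, 4]),
             stringsAsFactors = FALSE)
}

#' Count hits on the server
#' @inheritParams rdb_store_single
#' @param region a [region()] or \code{NULL} for the whole alignment.
#' @param filter a [hit_filter()].
#' @export
rdb_count <- function(con, align, region = NULL, filter = hit_filter()) {
  line <- rdb_request(con, paste0(
    "COUNT", do.call(kv, c(list(align = align), region_kv(region),
                           filter_kv(filter)))))
  as.integer(line[1])
}

#' Sum hit weights on the server
#' @inheritParams rdb_count
#' @export
rdb_weight_sum <- function(con, align, region = NULL,
                           filter = hit_filter()) {
  line <- rdb_request(con, paste0(
    "WEIGHTSUM", do.call(kv, c(list(align = align), region_kv(region),
                               filter_kv(filter)))))
  as.double(line[1])
}

#' Retrieve hits from the server
#' @inheritParams rdb_count
#' @param projection \code{"full"}, \code{"positions"} or
#'   \code{"weights"}.
#' @return hits data.frame, or a bare vector for narrow projections.
#' @export
rdb_get_hits <- function(con, align, region = NULL, filter = hit_filter(),
                         projection = "full") {
  lines <- rdb_request(con, paste0(
    "GETHITS", do.call(kv, c(list(align = align), region_kv(region),
                             filter_kv(filter),
                             list(projection = if (projection != "full")
                               projection)))))
  if (projection == "positions") return(as.integer(trimws(lines)))
  if (projection == "weights") return(as.double(lines))
  paired <- filter$endedness != "single"
  if (!base::length(lines)) return(empty_hits(paired))
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (paired)
    paired_hits(chrom = as.integer(m[, 1]), pos = as.integer(m[, 2]),
                strand = m[, 3], length = as.integer(m[, 4]),
                matechrom = as.integer(m[, 5]), matepos = as.integer(m[, 6]),
                matestrand = m[, 7], matelength = as.integer(m[, 8]),
                weight = as.double(m[, 9]))
  else
    single_hits(chrom = as.integer(m[, 1]), pos = as.integer(m[, 2]),
                strand = m[, 3], length = as.integer(m[, 4]),
                weight = as.double(m[, 5]))
}

#' Retrieve a server-side histogram
#' @inheritParams rdb_count
#' @param binwidth positive integer bin width in bases.
#' @param mode \code{"count"} or \code{"weight"}.
#' @return data.frame with \code{binstart} and \code{value}.
#' @export
rdb_histogram <- function(con, align, region, binwidth, mode = "count",
                          filter = hit_filter()) {
  lines <- rdb_request(con, paste0(
    "HISTOGRAM", do.call(kv, c(list(align = align), region_kv(region),
                               list(binwidth = binwidth, mode = mode),
                               filter_kv(filter)))))
  if (!base::length(lines))
    return(data.frame(binstart = integer(), value = numeric()))
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(binstart = as.integer(m[, 1]), value = as.double(m[, 2]))
}

#' Ask the server to shut down
#' @inheritParams rdb_store_single
#' @export
rdb_shutdown <- function(con) {
  try(rdb_request(con, "SHUTDOWN"), silent = TRUE)
  invisible(NULL)
}
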