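# TCP server speaking a line-oriented UTF-8 text protocol (PROTOCOL.md):
# one request line "VERB key=value ...", optionally followed by data
# lines for stores; one response "OK <n>" + n TSV lines, or
# "ERROR <code> <message>". Text in, text out: any language with a
# socket can query it.
#
# The server is a single-process event loop multiplexing concurrent
# client connections with socketSelect(); requests are executed one at a
# time, which serializes writes (single-writer, many-reader contract)
# while letting many clients hold connections open. Index files are
# cached in memory across requests (see cached_index), so repeated
# region queries touch only the data columns.

PROTOCOL_VERBS <- c("STORE", "STOREPAIRED", "DELETE", "CHROMS", "COUNT",
                    "WEIGHTSUM", "GETHITS", "HISTOGRAM", "SHUTDOWN")

#' Serve alignments over TCP
#'
#' Binds the port and answers protocol requests against alignments
#' stored under \code{root} (one subdirectory per alignment id) until a
#' SHUTDOWN request arrives. Malformed requests get an ERROR response
#' and the connection stays open; a request that stores data is
#' all-or-nothing.
#'
#' @param root data root directory containing alignment subdirectories.
#' @param port TCP port to listen on.
#' @param ready_file optional path touched once the socket is listening
#'   (lets a launcher wait for startup).
#' @return invisibly, the number of requests served.
#' @export
readdb_serve <- function(root, port, ready_file = NULL) {
  if (!dir.exists(root)) stop("root directory not readable: ", root)
  srv <- tryCatch(serverSocket(as.integer(port)),
                  error = function(e) stop("cannot bind port ", port, ": ",
                                           conditionMessage(e)))
  on.exit(close(srv), add = TRUE)
  if (!is.null(ready_file)) file.create(ready_file)
  clients <- list()
  served <- 0L
  repeat {
    polled <- clients
    ready <- socketSelect(c(list(srv), polled), timeout = 1)
    if (ready[1]) {
      con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 30)
      clients[[base::length(clients) + 1L]] <- con
    }
    drop <- integer()
    for (i in seq_along(polled)) {
      if (!ready[i + 1L]) next
      con <- polled[[i]]
      line <- tryCatch(readLines(con, n = 1L, warn = FALSE),
                       error = function(e) character())
      if (!base::length(line)) { drop <- c(drop, i); next }
      served <- served + 1L
      quit_now <- handle_request(root, con, line)
      if (quit_now) {
        for (c2 in clients) try(close(c2), silent = TRUE)
        return(invisible(served))
      }
    }
    if (base::length(drop)) {
      dead <- polled[drop]
      for (c2 in dead) try(close(c2), silent = TRUE)
      clients <- clients[!vapply(clients, function(x)
        any(vapply(dead, identical, TRUE, x = x)), TRUE)]
    }
  }
}

respond_ok <- function(con, lines = character()) {
  writeLines(c(paste("OK", base::length(lines)), lines), con, sep = "\n")
  flush(con)
}

respond_err <- function(con, code, msg) {
  msg <- gsub("[\r\n\t]+", " ", msg)
  writeLines(paste("ERROR", code, msg), con, sep = "\n")
  flush(con)
}

parse_request <- function(line) {
  toks <- strsplit(trimws(line), " +")[[1]]
  if (!base::length(toks)) return(NULL)
  verb <- toupper(toks[1])
  kv <- toks[-1]
  eq <- regexpr("=", kv, fixed = TRUE)
  params <- list()
  for (j in seq_along(kv)) {
    if (eq[j] < 1) return(NULL)
    params[[substr(kv[j], 1, eq[j] - 1)]] <- substr(kv[j], eq[j] + 1,
                                                    nchar(kv[j]))
  }
  list(verb = verb, params = params)
}

need <- function(p, ...) {
  for (k in c(...))
    if (is.null(p[[k]])) stop("missing required parameter: ", k)
  invisible(TRUE)
}

req_filter <- function(p) {
  hit_filter(strand = p$strand %||% "both",
             minweight = if (!is.null(p$minweight)) as.double(p$minweight),
             endedness = p$endedness %||% "single")
}

req_region <- function(align, p) {
  if (is.null(p$chrom)) return(NULL)
  ch <- resolve_chrom(align, p$chrom)
  if (is.null(p$start) && is.null(p$end)) return(region(ch, 1L, MAX_POS))
  region(ch, as.integer(p$start), as.integer(p$end))
}

align_dir_of <- function(root, id) {
  if (!grepl("^[A-Za-z0-9._-]+$", id) || grepl("^\\.", id))
    stop("invalid alignment id")
  file.path(root, id)
}

# Execute one request; returns TRUE when the server should shut down.
handle_request <- function(root, con, line) {
  req <- parse_request(line)
  if (is.null(req) || !nzchar(req$verb)) {
    respond_err(con, 400L, "malformed request")
    return(FALSE)
  }
  if (!(req$verb %in% PROTOCOL_VERBS)) {
    respond_err(con, 400L, "unknown verb")
    return(FALSE)
  }
  if (req$verb == "SHUTDOWN") { respond_ok(con); return(TRUE) }
  p <- req$params
  res <- tryCatch({
    switch(req$verb,
      STORE = h_store(root, con, p),
      STOREPAIRED = h_storepaired(root, con, p),
      DELETE = h_delete(root, p),
      CHROMS = h_chroms(root, p),
      COUNT = h_count(root, p),
      WEIGHTSUM = h_weightsum(root, p),
      GETHITS = h_gethits(root, p),
      HISTOGRAM = h_histogram(root, p))
  }, error = function(e) e)
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    code <- if (grepl("not found", msg)) 404L else 400L
    respond_err(con, code, msg)
  } else {
    respond_ok(con, res)
  }
  FALSE
}

# Read exactly n data lines from the connection (for stores).
read_payload <- function(con, n) {
  if (n == 0L) return(character())
  out <- character(0)
  while (base::length(out) < n) {
    got <- readLines(con, n = n - base::length(out), warn = FALSE)
    if (!base::length(got)) stop("connection closed mid-payload")
    out <- c(out, got)
  }
  out
}

h_store <- function(root, con, p) {
  need(p, "align", "chrom", "count")
  n <- as.integer(p$count)
  lines <- read_payload(con, n)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 4L)[1]
  if (!is.na(bad)) stop("parse failure on data line ", bad)
  m <- matrix(unlist(f), ncol = 4L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 1]))
  len <- suppressWarnings(as.integer(m[, 3]))
  w <- suppressWarnings(as.double(m[, 4]))
  bad <- which(is.na(pos) | is.na(len) | is.na(w) |
                 !(m[, 2] %in% c("+", "-")))[1]
  if (!is.na(bad)) stop("parse failure on data line ", bad)
  align <- align_open(align_dir_of(root, p$align))
  hits <- single_hits(chrom = resolve_chrom(align, p$chrom), pos = pos,
                      strand = m[, 2], length = len, weight = w)
  store_single(align, hits)   # validated above: all-or-nothing
  character()
}

h_storepaired <- function(root, con, p) {
  need(p, "align", "count")
  n <- as.integer(p$count)
  lines <- read_payload(con, n)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)[1]
  if (!is.na(bad)) stop("parse failure on data line ", bad)
  m <- matrix(unlist(f), ncol = 9L, byrow = TRUE)
  align <- align_open(align_dir_of(root, p$align))
  pairs <- paired_hits(
    chrom = as.integer(m[, 1]), pos = as.integer(m[, 2]), strand = m[, 3],
    length = as.integer(m[, 4]),
    matechrom = as.integer(m[, 5]), matepos = as.integer(m[, 6]),
    matestrand = m[, 7], matelength = as.integer(m[, 8]),
    weight = as.double(m[, 9]))
  store_paired(align, pairs)
  character()
}

open_existing <- function(root, id) {
  d <- align_dir_of(root, id)
  if (!dir.exists(d)) stop("alignment not found: ", id)
  d
}

h_delete <- function(root, p) {
  need(p, "align", "endedness")
  align <- open_existing(root, p$align)
  delete_hits(align, endedness = p$endedness,
              chrom = if (!is.null(p$chrom)) resolve_chrom(align, p$chrom))
  character()
}

h_chroms <- function(root, p) {
  need(p, "align")
  m <- alignment_meta(open_existing(root, p$align))
  sprintf("%d\t%s\t%d\t%d", m$chrom, m$name, m$single, m$paired)
}

h_count <- function(root, p) {
  need(p, "align")
  align <- open_existing(root, p$align)
  format(count_hits(align, req_region(align, p), req_filter(p)))
}

h_weightsum <- function(root, p) {
  need(p, "align")
  align <- open_existing(root, p$align)
  format(sum_weights(align, req_region(align, p), req_filter(p)),
         digits = 17)
}

h_gethits <- function(root, p) {
  need(p, "align")
  align <- open_existing(root, p$align)
  proj <- p$projection %||% "full"
  res <- get_hits(align, req_region(align, p), req_filter(p), proj)
  if (proj == "positions") return(format(res, scientific = FALSE))
  if (proj == "weights") return(format(res, digits = 9))
  if (inherits(res, "readstore_pairs"))
    sprintf("%d\t%d\t%s\t%d\t%d\t%d\t%s\t%d\t%s", res$chrom, res$pos,
            res$strand, res$length, res$matechrom, res$matepos,
            res$matestrand, res$matelength, format(res$weight, digits = 9))
  else
    sprintf("%d\t%d\t%s\t%d\t%s", res$chrom, res$pos, res$strand,
            res$length, format(res$weight, digits = 9))
}

h_histogram <- function(root, p) {
  need(p, "align", "chrom", "start", "end", "binwidth")
  align <- open_existing(root, p$align)
  h <- histogram_query(align, req_region(align, p),
                       binwidth = as.integer(p$binwidth),
                       mode = p$mode %||% "count", filter = req_filter(p))
  sprintf("%d\t%s", h$binstart, format(h$value, digits = 17))
}
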