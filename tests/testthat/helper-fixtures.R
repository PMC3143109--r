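# Shared fixtures: multiset keys for order-free comparison, a random
# store builder, and a background server launcher for the protocol
# tests.

# Canonical multiset key of a hit table (weights at float32 precision).
hit_key <- function(h) {
  sort(sprintf("%d:%d:%s:%d:%.7g", h$chrom, h$pos, h$strand, h$length,
               h$weight))
}

pair_key <- function(p) {
  sort(sprintf("%d:%d:%s:%d|%d:%d:%s:%d|%.7g", p$chrom, p$pos, p$strand,
               p$length, p$matechrom, p$matepos, p$matestrand, p$matelength,
               p$weight))
}

# Generate hits with gen_hits and load them into a fresh alignment;
# returns the align dir, the truth table and its brute-force oracle.
make_store <- function(seed = 1, n = 1000, nchrom = 1, weights = "uniform",
                       posrange = c(1L, 1000000L)) {
  g <- gen_hits(gen_spec(seed = seed, n = n, nchrom = nchrom,
                         weights = weights, posrange = posrange))
  d <- align_open(tempfile("store"))
  store_single(d, g$hits)
  list(align = d, hits = g$hits, oracle = g$oracle)
}

# Remap generator chromosome ids (chrN -> N) through an alignment's
# sidecar map, so generator truth is comparable with imported stores.
map_truth_chroms <- function(align, hits) {
  m <- chrom_map_read(align)
  hits$chrom <- m$id[match(sprintf("chr%d", hits$chrom), m$name)]
  hits
}

# Launch a server child process on a free port; returns list(port, root).
# The child is wrapped in a hard timeout so a failed test cannot leak a
# listener forever.
start_test_server <- function(root, timeout_s = 300) {
  for (attempt in 1:5) {
    port <- sample(42000:59999, 1)
    ready <- tempfile()
    script <- sprintf(
      ".libPaths(%s); suppressMessages(library(readstore)); readdb_serve(%s, %d, ready_file = %s)",
      paste(deparse(.libPaths()), collapse = ""),
      shQuote(root), port, shQuote(ready))
    system2("timeout", c(as.character(timeout_s), "Rscript", "-e",
                         shQuote(script)),
            wait = FALSE, stdout = FALSE, stderr = FALSE)
    for (i in 1:150) {
      if (file.exists(ready)) break
      Sys.sleep(0.1)
    }
    if (file.exists(ready)) return(list(root = root, port = port))
  }
  stop("test server failed to start")
}

# Convenience wrappers over internal store accessors.
part_n <- function(d, ch, p) readstore:::partition_count(d, ch, p)
store_chroms_pub <- function(d) readstore:::store_chroms(d)
partition_counts <- function(d) {
  ch <- store_chroms_pub(d)
  c(L = sum(vapply(ch, part_n, 0L, d = d, p = "pairedL")),
    R = sum(vapply(ch, part_n, 0L, d = d, p = "pairedR")))
}

stop_test_server <- function(srv) {
  con <- try(suppressWarnings(readdb_connect("localhost", srv$port,
                                             timeout = 5)),
             silent = TRUE)
  if (!inherits(con, "try-error")) {
    rdb_shutdown(con)
    try(readdb_disconnect(con), silent = TRUE)
  }
  invisible(NULL)
}
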