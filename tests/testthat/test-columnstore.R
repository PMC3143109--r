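# On-disk format: parallel column files, sorted merge-on-append writes,
# block index construction, paired dual keying, delete, verify.

read_bytes <- function(f) readBin(f, "raw", n = file.size(f))

test_that("writes sort by position and round-trip field-exact", {
  d <- align_open(tempfile())
  h <- single_hits(1, c(500L, 100L, 300L), c("+", "-", "+"), c(36L, 50L, 36L),
                   c(1.0, 0.1, 2.5))
  store_single(d, h)
  back <- read_records(d, 1, "single", 0, 3)
  expect_identical(back$pos, c(100L, 300L, 500L))
  expect_identical(back$strand, c("-", "+", "+"))
  expect_identical(back$length, c(50L, 36L, 36L))
  # weights at exactly float32 precision
  f32 <- readBin(writeBin(c(0.1, 2.5, 1.0), raw(), size = 4), "double",
                 n = 3, size = 4)
  expect_identical(back$weight, f32)
  expect_identical(nrow(read_records(d, 1, "single", 2, 2)), 0L)
  expect_error(read_records(d, 1, "single", 0, 4), "range")
})

test_that("appending merges into one sorted set, byte-identical to a bulk write", {
  d1 <- align_open(tempfile())
  store_single(d1, single_hits(1, 100L, "+", 36L, 1))
  store_single(d1, single_hits(1, 50L, "-", 30L, 0.5))
  expect_identical(read_records(d1, 1, "single", 0, 2)$pos, c(50L, 100L))
  d2 <- align_open(tempfile())
  store_single(d2, single_hits(1, c(50L, 100L), c("-", "+"), c(30L, 36L),
                               c(0.5, 1)))
  for (col in c("positions", "attrs", "weights", "index"))
    expect_identical(read_bytes(file.path(d1, paste0("1.single.", col))),
                     read_bytes(file.path(d2, paste0("1.single.", col))),
                     label = col)
})

test_that("writing any permutation of a hit multiset gives identical bytes", {
  set.seed(41)
  n <- 500L
  h <- single_hits(1, sample.int(1000L, n, replace = TRUE),
                   sample(c("+", "-"), n, TRUE),
                   sample(20:100, n, TRUE),
                   round(runif(n), 3))
  ref <- align_open(tempfile())
  store_single(ref, h)
  for (k in 1:3) {
    d <- align_open(tempfile())
    perm <- sample.int(n)
    # split the permutation into two appends as well
    cut <- n %/% 2
    store_single(d, h[perm[1:cut], ])
    store_single(d, h[perm[(cut + 1):n], ])
    expect_identical(read_bytes(file.path(d, "1.single.positions")),
                     read_bytes(file.path(ref, "1.single.positions")))
    expect_identical(read_bytes(file.path(d, "1.single.attrs")),
                     read_bytes(file.path(ref, "1.single.attrs")))
    expect_identical(read_bytes(file.path(d, "1.single.weights")),
                     read_bytes(file.path(ref, "1.single.weights")))
  }
})

test_that("column files respect the byte budget: 4+2+4 per record, 8 per index entry", {
  d <- align_open(tempfile())
  n <- 1000L
  g <- gen_hits(gen_spec(seed = 5, n = n))
  store_single(d, g$hits)
  expect_equal(file.size(file.path(d, "1.single.positions")), 4 * n)
  expect_equal(file.size(file.path(d, "1.single.attrs")), 2 * n)
  expect_equal(file.size(file.path(d, "1.single.weights")), 4 * n)
  expect_equal(file.size(file.path(d, "1.single.index")),
               8 * ceiling(n / 1024))
})

test_that("on-disk encoding is little-endian (golden bytes)", {
  d <- align_open(tempfile())
  store_single(d, single_hits(1, c(100L, 300L), c("+", "-"), c(36L, 50L),
                              c(1.0, 0.5)))
  expect_identical(read_bytes(file.path(d, "1.single.positions")),
                   as.raw(c(0x64, 0, 0, 0, 0x2c, 0x01, 0, 0)))
  # attrs: (+,36) = 0x0024; (-,50) = 0x8032
  expect_identical(read_bytes(file.path(d, "1.single.attrs")),
                   as.raw(c(0x24, 0x00, 0x32, 0x80)))
  # float32 LE: 1.0 = 0000803f, 0.5 = 0000003f
  expect_identical(read_bytes(file.path(d, "1.single.weights")),
                   as.raw(c(0, 0, 0x80, 0x3f, 0, 0, 0, 0x3f)))
  # one index entry: firstpos 100, offset 0
  expect_identical(read_bytes(file.path(d, "1.single.index")),
                   as.raw(c(0x64, 0, 0, 0, 0, 0, 0, 0)))
})

test_that("block index samples every 1024 records", {
  expect_identical(length(build_index(integer())$offset), 0L)
  idx <- build_index(sort(sample.int(1e6, 1025, replace = TRUE)))
  expect_identical(idx$offset, c(0L, 1024L))
  idx3 <- build_index(rep(7L, 3000))
  expect_identical(idx3$offset, c(0L, 1024L, 2048L))
  expect_identical(idx3$firstpos, rep(7L, 3))
  expect_error(build_index(c(5L, 3L)), "sorted")
})

test_that("paired stores are dual-keyed with anchor/mate swap bijection", {
  d <- align_open(tempfile())
  # one intra-chromosomal pair -> exactly 2 stored records
  store_paired(d, paired_hits(1, 100L, "+", 36L, 1, 260L, "-", 36L, 1.0))
  expect_identical(partition_counts(d), c(L = 1L, R = 1L))
  # interchromosomal pair routes to each end's chromosome
  d2 <- align_open(tempfile())
  store_paired(d2, paired_hits(1, 500L, "+", 36L, 2, 900L, "-", 36L, 1.0))
  expect_identical(nrow(read_records(d2, 1, "pairedL", 0, 1)), 1L)
  expect_identical(nrow(read_records(d2, 2, "pairedR", 0, 1)), 1L)
  expect_false(file.exists(file.path(d2, "2.pairedL.positions")))
  # random pairs: left/right partitions bijective under swap
  g <- gen_pairs(gen_spec(seed = 11, n = 300, nchrom = 3, paired = TRUE))
  d3 <- align_open(tempfile())
  store_paired(d3, g$pairs)
  L <- do.call(rbind, lapply(store_chroms_pub(d3), function(ch)
    read_records(d3, ch, "pairedL", 0, part_n(d3, ch, "pairedL"))))
  R <- do.call(rbind, lapply(store_chroms_pub(d3), function(ch)
    read_records(d3, ch, "pairedR", 0, part_n(d3, ch, "pairedR"))))
  expect_identical(nrow(L) + nrow(R), 2L * nrow(g$pairs))
  swapped <- R[, c("matechrom", "matepos", "matestrand", "matelength",
                   "chrom", "pos", "strand", "length", "weight")]
  names(swapped) <- names(L)
  expect_identical(pair_key(L), pair_key(swapped))
})

test_that("delete removes one partition, is idempotent, leaves the other intact", {
  d <- align_open(tempfile())
  store_single(d, single_hits(1, c(10L, 20L), "+", 36L, 1))
  store_paired(d, paired_hits(1, 100L, "+", 36L, 1, 300L, "-", 36L, 1))
  delete_hits(d, "single")
  expect_identical(count_hits(d), 0L)
  expect_identical(count_hits(d, filter = hit_filter(endedness = "paired-left")), 1L)
  expect_silent(delete_hits(d, "single"))  # idempotent
  delete_hits(d, "paired")
  expect_identical(count_hits(d, filter = hit_filter(endedness = "paired-left")), 0L)
  expect_error(delete_hits(tempfile("nope"), "single"), "not found")
})

test_that("verify_alignment detects truncation and unsorted positions", {
  d <- align_open(tempfile())
  store_single(d, single_hits(1, sort(sample.int(1e5, 2000)), "+", 36L, 1))
  expect_identical(verify_alignment(d), character())
  # truncate the weights column
  wf <- file.path(d, "1.single.weights")
  writeBin(readBin(wf, "raw", n = 100), wf)
  expect_match(verify_alignment(d), "weights", all = FALSE)
  # corrupt sort order in positions
  d2 <- align_open(tempfile())
  store_single(d2, single_hits(1, c(10L, 20L, 30L), "+", 36L, 1))
  pf <- file.path(d2, "1.single.positions")
  writeBin(c(30L, 20L, 10L), pf, size = 4, endian = "little")
  expect_match(verify_alignment(d2), "sorted|index", all = FALSE)
})
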