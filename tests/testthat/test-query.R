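# Indexed interval queries against the brute-force full-scan oracle.

test_that("locate clamps and seeks so no matching record precedes the offset", {
  idx <- structure(list(firstpos = c(100L, 900L), offset = c(0L, 1024L)),
                   class = "readstore_index")
  expect_identical(locate(idx, 950L), 1024L)
  expect_identical(locate(idx, 50L), 0L)
  expect_identical(locate(structure(list(firstpos = integer(),
                                         offset = integer()),
                                    class = "readstore_index"), 10L), 0L)
  # duplicated first positions across blocks: must not skip equal records
  dup <- structure(list(firstpos = c(100L, 100L, 200L),
                        offset = c(0L, 1024L, 2048L)),
                   class = "readstore_index")
  expect_identical(locate(dup, 100L), 0L)
})

test_that("region selection is inclusive and by stored 5' position", {
  d <- align_open(tempfile())
  store_single(d, single_hits(1, c(10L, 20L, 30L), "+", 36L, 1))
  expect_identical(get_hits(d, region(1, 15, 25))$pos, 20L)
  expect_identical(get_hits(d, region(1, 20, 20))$pos, 20L)
  # a minus-strand hit spanning into the region but with its 5' end
  # (pos 135, covering [100,135]) outside it is NOT returned
  d2 <- align_open(tempfile())
  store_single(d2, single_hits(1, 135L, "-", 36L, 1))
  expect_identical(nrow(get_hits(d2, region(1, 95, 120))), 0L)
  expect_identical(nrow(get_hits(d2, region(1, 120, 140))), 1L)
  # unknown chromosome is empty, not an error
  expect_identical(nrow(get_hits(d, region(99, 1, 100))), 0L)
  expect_identical(count_hits(d, region(99, 1, 100)), 0L)
})

test_that("filters: strand, inclusive minweight, projections", {
  d <- align_open(tempfile())
  store_single(d, single_hits(1, c(10L, 20L, 30L), c("+", "-", "+"), 36L,
                              c(0.5, 1.0, 2.0)))
  expect_identical(get_hits(d, region(1, 1, 100),
                            hit_filter(strand = "-"))$pos, 20L)
  got <- get_hits(d, region(1, 1, 100), hit_filter(minweight = 1.0))
  expect_identical(got$weight, c(1.0, 2.0))  # >= is inclusive
  expect_equal(get_hits(d, region(1, 1, 100), projection = "positions"),
               c(10L, 20L, 30L), ignore_attr = TRUE)
  expect_equal(get_hits(d, region(1, 1, 100), projection = "weights"),
               c(0.5, 1, 2), ignore_attr = TRUE)
})

test_that("randomized queries equal the brute-force oracle", {
  st <- make_store(seed = 101, n = 10000, nchrom = 2, weights = "uniform",
                   posrange = c(1L, 200000L))
  set.seed(202)
  for (i in 1:120) {
    ch <- sample(1:2, 1)
    a <- sample.int(200000L, 1)
    b <- min(200000L, a + sample.int(50000L, 1))
    reg <- region(ch, a, b)
    fl <- hit_filter(strand = sample(c("both", "+", "-"), 1),
                     minweight = if (runif(1) < 0.5) runif(1, 0, 2))
    want <- st$oracle$select(reg, fl)
    got <- get_hits(st$align, reg, fl)
    expect_identical(hit_key(got), hit_key(want))
    expect_identical(count_hits(st$align, reg, fl), nrow(want))
    expect_equal(sum_weights(st$align, reg, fl), sum(want$weight),
                 tolerance = 1e-6)
    expect_equal(get_hits(st$align, reg, fl, "positions"),
                 sort(want$pos), ignore_attr = TRUE)
    bw <- sample.int(5000L, 1)
    mode <- sample(c("count", "weight"), 1)
    expect_equal(histogram_query(st$align, reg, bw, mode, fl),
                 st$oracle$hist(reg, bw, mode, fl), tolerance = 1e-9)
  }
})

test_that("count and sum over the whole store are conserved and additive", {
  st <- make_store(seed = 7, n = 5000, posrange = c(1L, 100000L))
  expect_identical(count_hits(st$align), 5000L)
  expect_equal(sum_weights(st$align), sum(st$hits$weight), tolerance = 1e-9)
  # additivity over a random partition of the chromosome
  set.seed(9)
  cuts <- sort(sample(2:99999, 5))
  bounds <- cbind(c(1L, cuts + 1L), c(cuts, 100000L))
  parts <- vapply(seq_len(nrow(bounds)), function(i)
    count_hits(st$align, region(1, bounds[i, 1], bounds[i, 2])), 0L)
  expect_identical(sum(parts), 5000L)
  # empty region before the first hit
  first <- min(st$hits$pos)
  if (first > 1)
    expect_identical(count_hits(st$align, region(1, 1, first - 1L)), 0L)
})

test_that("histogram bins anchor at region start and conserve totals", {
  d <- align_open(tempfile())
  store_single(d, single_hits(1, c(5L, 15L, 25L), "+", 4L, 1))
  h <- histogram_query(d, region(1, 1, 30), 10)
  expect_identical(h$binstart, c(1L, 11L, 21L))
  expect_identical(h$value, c(1, 1, 1))
  # degenerate: one bin spanning the region
  h1 <- histogram_query(d, region(1, 1, 30), 30)
  expect_identical(h1$binstart, 1L)
  expect_identical(h1$value, 3)
  expect_error(histogram_query(d, region(1, 1, 30), 0), "binwidth")
  # conservation across random regions and binwidths
  st <- make_store(seed = 55, n = 8000, posrange = c(1L, 50000L))
  set.seed(56)
  for (i in 1:30) {
    a <- sample.int(50000L, 1); b <- min(50000L, a + sample.int(20000L, 1))
    reg <- region(1, a, b); bw <- sample.int(3000L, 1)
    expect_identical(sum(histogram_query(st$align, reg, bw, "count")$value),
                     as.double(count_hits(st$align, reg)))
    expect_equal(sum(histogram_query(st$align, reg, bw, "weight")$value),
                 sum_weights(st$align, reg), tolerance = 1e-6)
  }
})

test_that("decode work is bounded by result size plus two index blocks", {
  st <- make_store(seed = 77, n = 50000, posrange = c(1L, 5000000L))
  set.seed(78)
  for (i in 1:40) {
    a <- sample.int(5000000L, 1)
    b <- min(5000000L, a + sample.int(500000L, 1))
    got <- get_hits(st$align, region(1, a, b))
    expect_lte(attr(got, "records_decoded"), nrow(got) + 2L * 1024L)
  }
})

test_that("list_chromosomes reflects stored partitions and deletes", {
  d <- align_open(tempfile())
  store_single(d, single_hits(c(1L, 5L), c(10L, 20L), "+", 36L, 1))
  expect_identical(list_chromosomes(d)$chrom, c(1L, 5L))
  delete_hits(d, "single", chrom = 5L)
  expect_identical(list_chromosomes(d)$chrom, 1L)
  empty <- align_open(tempfile())
  expect_identical(nrow(list_chromosomes(empty)), 0L)
  expect_error(list_chromosomes(tempfile("gone")), "not found")
})
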