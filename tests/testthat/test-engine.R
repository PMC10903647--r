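test_that("overlap kernel handles the half-open boundary cases", {
  expect_identical(ivl_overlap_pairs(0L, 10L, 5L, 15L),
                   tibble::tibble(id_a = 1L, id_b = 1L))
  expect_identical(nrow(ivl_overlap_pairs(0L, 10L, 10L, 20L)), 0L)  # bookended
  # zero-length: overlaps only when strictly inside
  expect_identical(nrow(ivl_overlap_pairs(5L, 5L, 3L, 8L)), 1L)
  expect_identical(nrow(ivl_overlap_pairs(5L, 5L, 5L, 8L)), 0L)
  expect_identical(nrow(ivl_overlap_pairs(5L, 5L, 3L, 5L)), 0L)
  expect_identical(nrow(ivl_overlap_pairs(5L, 5L, 5L, 5L)), 0L)
  expect_identical(nrow(ivl_overlap_pairs(integer(), integer(), 1L, 2L)), 0L)
})

test_that("overlap kernel agrees with the all-pairs oracle and is symmetric", {
  for (seed in 1:12) {
    a <- random_intervals(200, c(c1 = 1e4), length_range = c(0, 120),
                          seed = 100 + seed)
    b <- random_intervals(300, c(c1 = 1e4), length_range = c(0, 120),
                          seed = 200 + seed)
    got <- ivl_overlap_pairs(a$start, a$end, b$start, b$end)
    exp <- oracle_overlap(a, b)
    expect_identical(as.data.frame(got), as.data.frame(exp))
    # symmetry: pairs(A,B) is the transpose of pairs(B,A)
    rev <- ivl_overlap_pairs(b$start, b$end, a$start, a$end)
    rev <- rev[order(rev$id_b, rev$id_a), ]
    expect_identical(unname(got$id_a), unname(rev$id_b))
    expect_identical(unname(got$id_b), unname(rev$id_a))
  }
})

test_that("sweep merge joins bookended intervals at distance 0 only", {
  res <- ivl_cluster(c(0L, 10L), c(10L, 20L), min_dist = 0L)
  expect_identical(res$cluster, c(1L, 1L))
  expect_identical(res$run_start, 0L)
  expect_identical(res$run_end, 20L)
  res <- ivl_cluster(c(0L, 10L), c(10L, 20L), min_dist = NULL)
  expect_identical(res$cluster, c(1L, 2L))
  expect_error(ivl_cluster(0L, 1L, min_dist = -1), class = "bf_error_engine")
})

test_that("sweep merge matches union-find components on random input", {
  for (seed in 1:8) {
    x <- random_intervals(500, c(c1 = 2e4), length_range = c(0, 60),
                          seed = 300 + seed)
    for (md in list(NULL, 0L, 7L)) {
      got <- ivl_cluster(x$start, x$end, min_dist = md)
      exp <- brute_cluster(x$chrom, x$start, x$end, md)
      expect_identical(got$cluster, exp)
      # runs are sorted and non-overlapping; total length matches the bitmap
      expect_true(all(diff(got$run_start) >= 0))
      if (is.null(md)) {
        n_runs <- length(got$run_start)
        if (n_runs > 1L) {
          expect_true(all(got$run_start[-1L] >= got$run_end[-n_runs]))
        }
        lookup <- brute_bitmap(x, 2e4)
        expect_identical(sum(got$run_end - got$run_start),
                         lookup("c1", 0L, 20000L))
      }
    }
  }
})

test_that("nearest kernel matches brute-force ranking with tie-breaks", {
  expect_identical(ivl_nearest(0L, 10L, c(20L, 40L), c(30L, 50L), k = 1),
                   tibble::tibble(id_a = 1L, id_b = 1L, distance = 10))
  expect_identical(ivl_nearest(0L, 10L, 5L, 15L, k = 1)$distance, 0)
  for (seed in 1:10) {
    a <- random_intervals(100, c(c1 = 8e3), length_range = c(0, 80),
                          seed = 400 + seed)
    b <- random_intervals(100, c(c1 = 8e3), length_range = c(0, 80),
                          seed = 500 + seed)
    for (k in c(1L, 2L)) {
      got <- as.data.frame(ivl_nearest(a$start, a$end, b$start, b$end, k = k))
      exp <- brute_closest(a, b, k = k)
      expect_equal(got, exp, ignore_attr = TRUE)
    }
    got <- as.data.frame(ivl_nearest(a$start, a$end, b$start, b$end, k = 2L,
                                     include_overlaps = FALSE,
                                     include_upstream = FALSE))
    exp <- brute_closest(a, b, k = 2L, ignore_overlaps = TRUE,
                         ignore_upstream = TRUE)
    expect_equal(got, exp, ignore_attr = TRUE)
  }
})

test_that("complement inverts coverage exactly within bounds", {
  expect_identical(ivl_complement(10L, 20L, 0L, 30L),
                   tibble::tibble(start = c(0L, 20L), end = c(10L, 30L)))
  expect_identical(nrow(ivl_complement(0L, 30L, 0L, 30L)), 0L)
  expect_identical(ivl_complement(integer(), integer(), 0L, 5L),
                   tibble::tibble(start = 0L, end = 5L))
  for (seed in 1:8) {
    x <- random_intervals(300, c(c1 = 1e5), length_range = c(0, 700),
                          seed = 600 + seed)
    gaps <- ivl_complement(x$start, x$end, 0L, 100000L)
    lookup <- brute_bitmap(x, 1e5)
    expect_identical(sum(gaps$end - gaps$start),
                     100000L - lookup("c1", 0L, 100000L))
    # gaps and merged runs tile the bounds exactly
    runs <- ivl_cluster(x$start, x$end, min_dist = NULL)
    covered <- sum(runs$run_end - runs$run_start)
    expect_identical(sum(gaps$end - gaps$start) + covered, 100000L)
    pos <- runs$run_end > runs$run_start  # zero-length runs cover nothing
    both <- rbind(gaps, tibble::tibble(start = runs$run_start[pos],
                                       end = runs$run_end[pos]))
    prs <- ivl_overlap_pairs(both$start, both$end, both$start, both$end)
    expect_true(all(prs$id_a == prs$id_b))  # pairwise disjoint
  }
})

test_that("merged runs agree with an independent interval library", {
  # second opinion from IRanges::reduce (implementation remains our own)
  x <- random_intervals(400, c(c1 = 5e4), length_range = c(1, 300), seed = 700)
  runs <- ivl_cluster(x$start, x$end, min_dist = 0L)
  red <- IRanges::reduce(IRanges::IRanges(start = x$start + 1L, end = x$end))
  expect_identical(runs$run_start, IRanges::start(red) - 1L)
  expect_identical(runs$run_end, IRanges::end(red))
})
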