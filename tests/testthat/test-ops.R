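test_that("overlap join respects grouping columns and join modes", {
  a <- bf_tbl("chr1", 0, 10, strand = "+")
  b <- bf_tbl("chr1", 5, 15, strand = "-")
  expect_identical(nrow(bf_overlap(a, b, on = "strand")), 0L)

  res <- bf_overlap(a, b, how = "left", return_overlap = TRUE)
  expect_identical(nrow(res), 1L)
  expect_identical(res$overlap_start, 5L)
  expect_identical(res$overlap_end, 10L)
  expect_identical(res$overlap_length, 5L)

  # left mode keeps unmatched left rows with missing right columns
  a2 <- bf_tbl("chr1", c(0, 50), c(10, 60), id = c("x", "y"))
  res <- bf_overlap(a2, b, how = "left")
  expect_identical(nrow(res), 2L)
  expect_identical(res$id, c("x", "y"))
  expect_true(is.na(res$start_[res$id == "y"]))

  # outer additionally keeps unmatched right rows
  b2 <- bf_tbl(c("chr1", "chr2"), c(5, 0), c(15, 5))
  res <- bf_overlap(a2, b2, how = "outer")
  expect_identical(nrow(res), 3L)
  expect_true(any(is.na(res$start) & res$chrom_ == "chr2"))

  # errors: missing `on` column, suffix collisions
  expect_error(bf_overlap(a, b, on = "missing_col"),
               regexp = "left", class = "bf_error_validation")
  expect_error(bf_overlap(a, b, suffixes = c("", "")),
               regexp = "duplicate", class = "bf_error_validation")
})

test_that("overlap matches the brute-force join on random multichrom input", {
  a <- random_intervals(300, c(chr1 = 2e4, chr2 = 2e4, chr3 = 1e4),
                        length_range = c(0, 200), seed = 11)
  b <- random_intervals(300, c(chr1 = 2e4, chr2 = 2e4, chr3 = 1e4),
                        length_range = c(0, 200), seed = 12)
  res <- bf_overlap(a, b, how = "inner", return_index = TRUE)
  exp <- oracle_overlap(a, b)
  expect_identical(res$index, exp$id_a)
  expect_identical(res$index_, exp$id_b)
})

test_that("rows with missing coordinates reappear as unmatched join rows", {
  a <- tibble::tibble(chrom = c("chr1", "chr1"), start = c(0L, NA),
                      end = c(10L, NA), id = c("ok", "na"))
  b <- bf_tbl("chr1", 5, 15)
  expect_identical(bf_overlap(a, b, how = "inner")$id, "ok")
  res <- bf_overlap(a, b, how = "left")
  expect_identical(sort(res$id), c("na", "ok"))
  expect_true(is.na(res$start_[res$id == "na"]))
})

test_that("cluster assigns dense transitive ids within partitions", {
  x <- bf_tbl("chr1", c(0, 5, 30), c(10, 20, 40))
  res <- bf_cluster(x, min_dist = 0)
  expect_identical(res$cluster, c(1L, 1L, 2L))
  expect_identical(res$cluster_start, c(0L, 0L, 30L))
  expect_identical(res$cluster_end, c(20L, 20L, 40L))

  x <- bf_tbl(c("chr1", "chr2"), c(0, 0), c(10, 10))
  expect_identical(bf_cluster(x)$cluster, c(1L, 2L))

  # strand partition via `on`
  x <- bf_tbl("chr1", c(0, 5), c(10, 20), strand = c("+", "-"))
  expect_identical(bf_cluster(x, on = "strand")$cluster, c(1L, 2L))

  expect_error(bf_cluster(x, min_dist = -2), class = "bf_error_engine")

  x <- random_intervals(400, c(chr1 = 3e4, chr2 = 2e4),
                        length_range = c(0, 120), seed = 13)
  expect_identical(bf_cluster(x, min_dist = 7)$cluster,
                   brute_cluster(x$chrom, x$start, x$end, 7))
})

test_that("merge produces sorted disjoint runs and is idempotent", {
  x <- bf_tbl("chr1", c(0, 5), c(10, 20))
  res <- bf_merge(x)
  expect_identical(res, tibble::tibble(chrom = "chr1", start = 0L, end = 20L,
                                       n_intervals = 2L))
  y <- random_intervals(400, c(chr1 = 3e4, chr2 = 2e4),
                        length_range = c(0, 150), seed = 14)
  m1 <- bf_merge(y)
  m2 <- bf_merge(m1[names(m1) != "n_intervals"])
  expect_identical(m1[1:3], m2[1:3])
  lookup <- brute_bitmap(y, 3e4)
  expect_identical(sum(m1$end - m1$start),
                   lookup("chr1", 0L, 30000L) + lookup("chr2", 0L, 30000L))
})

test_that("closest ranks partners by distance with deterministic tie-breaks", {
  g <- bf_tbl("chr1", 100, 200)
  p <- bf_tbl("chr1", c(0, 300), c(50, 400))
  expect_identical(bf_closest(g, p)$distance, 50)
  expect_identical(bf_closest(g, p, ignore_upstream = TRUE)$distance, 100)

  # no eligible partner -> missing right side, missing distance
  res <- bf_closest(g, p, ignore_upstream = TRUE, ignore_downstream = TRUE)
  expect_identical(nrow(res), 1L)
  expect_true(is.na(res$distance))

  # self mode never pairs a row with itself
  res <- bf_closest(p)
  expect_identical(res$start_, c(300L, 0L))
  expect_identical(res$distance, c(250, 250))

  a <- random_intervals(150, c(chr1 = 1e4, chr2 = 8e3),
                        length_range = c(0, 90), seed = 15)
  b <- random_intervals(150, c(chr1 = 1e4, chr2 = 8e3),
                        length_range = c(0, 90), seed = 16)
  res <- bf_closest(a, b, k = 3)
  res <- res[!is.na(res$distance), ]
  exp <- brute_closest(a, b, k = 3)
  expect_identical(res$start_, b$start[exp$id_b])
  expect_identical(res$distance, exp$distance)
})

test_that("complement returns cataloged gaps in view order", {
  view <- bf_make_view(c(p = "chr1:0-100"))
  res <- bf_complement(bf_tbl(character(), integer(), integer()), view)
  expect_identical(res$start, 0L)
  expect_identical(res$end, 100L)
  expect_identical(res$view_region, "p")
  expect_identical(nrow(bf_complement(bf_tbl("chr1", 0, 100), view)), 0L)
  # intervals on chroms outside the view are ignored but counted
  res <- bf_complement(bf_tbl("chr9", 0, 10), view)
  expect_identical(attr(res, "bf_ignored"), 1L)
})

test_that("coverage counts union bases and count counts intervals", {
  left <- bf_tbl("chr1", 0, 100)
  right <- bf_tbl("chr1", c(10, 15), c(20, 30))
  expect_identical(bf_coverage(left, right)$coverage, 20L)
  expect_identical(bf_coverage(left, right[0, ])$coverage, 0L)

  expect_identical(
    bf_count_overlaps(bf_tbl("chr1", 0, 10),
                      bf_tbl("chr1", c(5, 9), c(6, 12)))$count, 2L)
  expect_identical(
    bf_count_overlaps(bf_tbl("chr1", 0, 10), bf_tbl("chr1", 10, 20))$count, 0L)

  a <- random_intervals(200, c(chr1 = 2e4), length_range = c(0, 300), seed = 17)
  b <- random_intervals(200, c(chr1 = 2e4), length_range = c(0, 300), seed = 18)
  lookup <- brute_bitmap(b, 2e4)
  expect_identical(bf_coverage(a, b)$coverage,
                   vapply(seq_len(nrow(a)),
                          function(i) lookup("chr1", a$start[i], a$end[i]),
                          integer(1)))
  exp <- oracle_overlap(a, b)
  expect_identical(bf_count_overlaps(a, b)$count,
                   tabulate(exp$id_a, nbins = nrow(a)))
})

test_that("expand pads, scales and collapses inverted intervals", {
  x <- bf_tbl("chr1", 10, 20)
  expect_identical(bf_expand(x, pad = 5)$start, 5L)
  expect_identical(bf_expand(x, pad = 5)$end, 25L)
  res <- bf_expand(x, pad = -10)
  expect_identical(c(res$start, res$end), c(15L, 15L))
  res <- bf_expand(x, scale = 2)
  expect_identical(c(res$start, res$end), c(5L, 25L))
  res <- bf_expand(x, scale = 0.5)
  expect_identical(res$end - res$start, 5L)
  res <- bf_expand(x, pad = 5, side = "left")
  expect_identical(c(res$start, res$end), c(5L, 20L))
  expect_error(bf_expand(x, pad = 1, scale = 1), class = "bf_error_validation")
  expect_error(bf_expand(x), class = "bf_error_validation")
  # negative coordinates are allowed; trimming is explicit
  expect_identical(bf_expand(bf_tbl("chr1", 2, 4), pad = 5)$start, -3L)
})

test_that("subtract splits around covered bases and conserves length", {
  left <- bf_tbl("chr1", 0, 100, id = "a")
  right <- bf_tbl("chr1", 40, 60)
  res <- bf_subtract(left, right)
  expect_identical(res$start, c(0L, 60L))
  expect_identical(res$end, c(40L, 100L))
  expect_identical(res$id, c("a", "a"))
  expect_identical(nrow(bf_subtract(left, bf_tbl("chr1", 0, 100))), 0L)

  a <- random_intervals(200, c(chr1 = 2e4), length_range = c(0, 250), seed = 19)
  b <- random_intervals(200, c(chr1 = 2e4), length_range = c(0, 250), seed = 20)
  a$row_id <- seq_len(nrow(a))
  rem <- bf_subtract(a, b)
  rem_len <- vapply(split(rem$end - rem$start, rem$row_id), sum, numeric(1))
  lens <- rep(0, nrow(a))
  lens[as.integer(names(rem_len))] <- rem_len
  cov <- bf_coverage(a, b)$coverage
  expect_identical(as.integer(lens + cov), as.integer(a$end - a$start))
})

test_that("setdiff removes whole overlapping rows only", {
  left <- bf_tbl("chr1", c(0, 20), c(10, 30))
  right <- bf_tbl("chr1", 5, 6)
  expect_identical(bf_setdiff(left, right)$start, 20L)
  expect_identical(bf_setdiff(left, right[0, ]), left)
  a <- random_intervals(300, c(chr1 = 2e4), length_range = c(0, 150), seed = 21)
  b <- random_intervals(300, c(chr1 = 2e4), length_range = c(0, 150), seed = 22)
  exp <- a[setdiff(seq_len(nrow(a)), oracle_overlap(a, b)$id_a), ]
  expect_identical(bf_setdiff(a, b), exp)
})

test_that("trim clips to assigned regions and drops empty intersections", {
  view <- bf_make_view(c(p = "chr1:0-100"))
  res <- bf_trim(bf_tbl("chr1", -5, 50), view)
  expect_identical(c(res$start, res$end), c(0L, 50L))
  res <- bf_trim(bf_tbl("chr1", 150, 160), view)
  expect_identical(nrow(res), 0L)
  expect_identical(attr(res, "bf_dropped"), 1L)
  # rows on chroms with no region are dropped, not an error
  res <- bf_trim(bf_tbl("chrZ", 0, 10), view)
  expect_identical(nrow(res), 0L)
  # idempotence
  x <- random_intervals(200, c(chr1 = 5e3), length_range = c(0, 100), seed = 23)
  x$start <- x$start - 50L  # push some out of bounds
  view2 <- bf_make_view(c(chr1 = 4000))
  t1 <- bf_trim(x, view2)
  t2 <- bf_trim(t1, view2)
  attr(t1, "bf_dropped") <- attr(t2, "bf_dropped") <- NULL
  expect_identical(t1, t2)
})

test_that("select returns rows overlapping a parsed region", {
  x <- bf_tbl("chr1", c(0, 10), c(10, 20))
  expect_identical(bf_select(x, "chr1:5-10")$start, 0L)  # bookended excluded
  expect_identical(nrow(bf_select(x, "chr2")), 0L)
  expect_identical(nrow(bf_select(x, "chr1")), 2L)
  expect_identical(bf_select(x, "chr1:0-15", contained = TRUE)$start, 0L)
  expect_error(bf_select(x, "chr1:20-10"), class = "bf_error_io")
  y <- random_intervals(300, c(chr1 = 1e4), length_range = c(0, 80), seed = 24)
  hit <- bf_select(y, "chr1:4000-5000")
  exp <- y[y$start < 5000 & y$end > 4000, ]
  expect_identical(hit, exp)
})

test_that("operations are congruent with per-partition execution", {
  a <- random_intervals(200, c(chr1 = 1e4), length_range = c(0, 100),
                        strand_prob = c(0.5, 0.5), seed = 25)
  b <- random_intervals(200, c(chr1 = 1e4), length_range = c(0, 100),
                        strand_prob = c(0.5, 0.5), seed = 26)
  whole <- bf_overlap(a, b, on = "strand", how = "inner")
  parts <- lapply(c("+", "-"), function(st) {
    bf_overlap(a[a$strand == st, ], b[b$strand == st, ], how = "inner")
  })
  manual <- vctrs::vec_rbind(parts[[1]], parts[[2]])
  key <- function(d) d[order(d$start, d$end, d$start_, d$end_), ]
  expect_identical(key(whole), key(manual))
})

test_that("annotation columns pass through operations untouched", {
  a <- random_intervals(120, c(chr1 = 1e4), length_range = c(1, 100), seed = 27)
  a$tag <- sample(letters, nrow(a), replace = TRUE)
  a$wt <- rnorm(nrow(a))
  a$fct <- factor(sample(c("u", "v"), nrow(a), TRUE))
  ann <- c("tag", "wt", "fct")
  # row-preserving operations: annotation values and types identical
  for (res in list(bf_cluster(a), bf_coverage(a, a),
                   bf_count_overlaps(a, a))) {
    expect_identical(res[ann], a[ann])
  }
  # row-permuting operation: annotations travel with their rows
  res <- bf_sort(a)
  perm <- order(a$chrom, a$start, a$end, method = "radix")
  expect_identical(res[ann], a[perm, ann])
})
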