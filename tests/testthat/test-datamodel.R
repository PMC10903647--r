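test_that("bedframe validation accepts valid tables and reports violations", {
  expect_true(is_bedframe(bf_tbl("chr1", 0, 10)))
  expect_true(is_bedframe(bf_tbl("chr1", 5, 5)))  # zero-length is valid

  chk <- check_bedframe(bf_tbl("chr1", 10, 0))
  expect_false(chk$valid)
  expect_identical(chk$violations$row, 1L)
  expect_match(chk$violations$violation, "start>end")

  # rows with all coordinates missing are fine; partial missingness is not
  expect_true(is_bedframe(bf_tbl(NA, NA, NA)))
  chk <- check_bedframe(bf_tbl("chr1", NA, 10))
  expect_false(chk$valid)
  expect_match(chk$violations$violation, "partially missing")
  chk <- check_bedframe(bf_tbl(NA, 0, 10))
  expect_match(chk$violations$violation, "chrom missing")

  # non-integer coordinates
  expect_false(is_bedframe(tibble::tibble(chrom = "chr1", start = 0.5, end = 2)))
  expect_true(is_bedframe(tibble::tibble(chrom = "chr1", start = 3, end = 7)))
})

test_that("missing coordinate columns are a schema-absent outcome, not a report", {
  chk <- check_bedframe(tibble::tibble(foo = 1))
  expect_false(chk$valid)
  expect_false(chk$schema_present)
  expect_identical(nrow(chk$violations), 0L)
})

test_that("viewframe validation enforces names, coordinates and disjointness", {
  expect_true(is_viewframe(bf_tbl("chr1", c(0, 100), c(100, 200),
                                  name = c("p", "q"))))  # bookended ok
  chk <- check_viewframe(bf_tbl("chr1", c(0, 50), c(100, 200),
                                name = c("p", "q")))
  expect_false(chk$valid)
  expect_match(chk$violations$violation, "overlapping")
  chk <- check_viewframe(bf_tbl(c("chr1", "chr2"), c(0, 0), c(100, 50),
                                name = c("p", "p")))
  expect_false(chk$valid)
  expect_match(chk$violations$violation, "duplicate")
  expect_false(is_viewframe(bf_tbl("chr1", NA, 10, name = "p")))
  # several regions may share a chromosome
  expect_true(is_viewframe(bf_tbl("chr1", c(0, 60), c(60, 100),
                                  name = c("p", "q"))))
})

test_that("sanitize coerces text coordinates and optionally drops bad rows", {
  out <- bf_sanitize(data.frame(chrom = "chr1", start = "5", end = "10"))
  expect_identical(out$start, 5L)
  expect_identical(out$end, 10L)

  out <- bf_sanitize(bf_tbl("chr1", 10, 2), drop_invalid = TRUE)
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "bf_dropped"), 1L)

  out <- bf_sanitize(bf_tbl("chr1", NA, 10), drop_invalid = TRUE)
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "bf_dropped"), 1L)

  expect_error(
    bf_sanitize(data.frame(chrom = "chr1", start = "abc", end = "10")),
    regexp = "start.*abc.*row 1", class = "bf_error_validation")

  # identity on already-valid complete tables
  x <- bf_tbl(c("chr1", "chr2"), c(0, 7), c(10, 7), score = c(1.5, 2.5))
  out <- bf_sanitize(x, drop_invalid = TRUE)
  expect_identical(out$start, x$start)
  expect_identical(out$end, x$end)
  expect_identical(out$score, x$score)
  expect_identical(attr(out, "bf_dropped"), 0L)
})

test_that("validation does not mutate its input", {
  x <- bf_tbl("chr1", c(10, 0), c(0, 5))
  snapshot <- data.frame(x)
  invisible(check_bedframe(x))
  invisible(is_viewframe(x))
  invisible(bf_sanitize(x))
  expect_identical(data.frame(x), snapshot)
})

test_that("checks suite classifies sortedness, overlap, covering and tiling", {
  view <- bf_make_view(c(p = "chr1:0-100"))

  tiles <- bf_tbl("chr1", c(0, 40), c(40, 100))
  expect_true(bf_is_tiling(tiles, view))
  res <- bf_checks(tiles, view)
  expect_true(res[["is_sorted"]])
  expect_false(res[["is_overlapping"]])
  expect_true(res[["is_covering"]])
  expect_true(res[["is_tiling"]])

  # covering with overlap: union still covers all 100 bases, but not tiling
  lapping <- bf_tbl("chr1", c(0, 40), c(50, 100))
  expect_identical(oracle_union_bases(lapping, c(0, 100)), 100L)
  expect_true(bf_is_covering(lapping, view))
  expect_true(bf_is_overlapping(lapping))
  expect_false(bf_is_tiling(lapping, view))

  empty <- bf_tbl(character(), integer(), integer())
  expect_false(bf_is_covering(empty, view))
  expect_false(bf_is_overlapping(empty))

  # cataloged / contained need an assignment column
  expect_error(bf_is_cataloged(tiles, view), class = "bf_error_assignment")
  assigned <- bf_assign_view(tiles, view)
  expect_true(bf_is_cataloged(assigned, view))
  expect_true(bf_is_contained(assigned, view))
  stray <- assigned
  stray$view_region[1] <- "nope"
  expect_false(bf_is_cataloged(stray, view))
})

test_that("is_sorted follows view order when a view is given", {
  view <- bf_make_view(c(chr2 = 50, chr1 = 100))
  x <- bf_tbl(c("chr2", "chr1"), c(0, 0), c(10, 10))
  expect_true(bf_is_sorted(x, view))
  expect_false(bf_is_sorted(x))          # lexicographic says chr1 first
  expect_true(bf_is_sorted(bf_sort(x)))
})
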