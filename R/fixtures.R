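# Seeded random-interval generation, brute-force oracles, and the scaling
# benchmark. The oracles are deliberately naive (all-pairs double loop,
# per-base bitmap) and share no code with the engine kernels; they exist to
# be referenced from tests and the benchmark, never from library code paths.

#' Generate random genomic intervals
#'
#' Deterministic given `seed`. Chromosomes are sampled proportional to their
#' length; interval lengths uniform integers in `length_range`; starts
#' uniform in `[0, chrom length - interval length]`, so every interval fits
#' its chromosome. The defaults emulate a human-scale genome slice: three
#' chromosomes of 250/200/150 Mb and lengths 1–10000 bp.
#'
#' @param n Number of intervals (`n = 0` gives a valid empty table).
#' @param chromsizes Named numeric vector of chromosome lengths.
#' @param length_range Length-2 integer vector `c(min, max)` (equal values
#'   give fixed-length intervals).
#' @param strand_prob `NULL`, or probabilities for `c("+", "-")` (need not
#'   sum to 1; the remainder is `"."`) — adds a `strand` column.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @param sorted Sort the output by (chrom, start, end).
#' @param cols Coordinate column names for the result.
#' @return A bedframe tibble.
#' @examples
#' random_intervals(3, chromsizes = c(chrA = 1000), seed = 1)
#' @export
random_intervals <- function(n,
                             chromsizes = c(chr1 = 250e6, chr2 = 200e6,
                                            chr3 = 150e6),
                             length_range = c(1, 10000),
                             strand_prob = NULL, seed = NULL,
                             sorted = FALSE, cols = NULL) {
  cols <- resolve_cols(cols)
  if (!is.numeric(chromsizes) || is.null(names(chromsizes)) ||
      !length(chromsizes)) {
    rlang::abort("`chromsizes` must be a named numeric vector.",
                 class = "bf_error_validation")
  }
  if (length(length_range) == 1L) length_range <- rep(length_range, 2L)
  if (length_range[1L] < 0 || length_range[1L] > length_range[2L]) {
    rlang::abort("`length_range` must satisfy 0 <= min <= max.",
                 class = "bf_error_validation")
  }
  if (length_range[2L] > min(chromsizes)) {
    rlang::abort("maximum interval length exceeds the smallest chromosome.",
                 class = "bf_error_validation")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n <- as.integer(n)
  chr_idx <- sample.int(length(chromsizes), n, replace = TRUE,
                        prob = chromsizes / sum(chromsizes))
  len <- sample.int(length_range[2L] - length_range[1L] + 1L, n,
                    replace = TRUE) - 1L + as.integer(length_range[1L])
  max_start <- as.integer(chromsizes[chr_idx]) - len
  start <- as.integer(floor(stats::runif(n) * (max_start + 1)))
  out <- tibble::tibble(!!cols[1L] := names(chromsizes)[chr_idx],
                        !!cols[2L] := start,
                        !!cols[3L] := start + len)
  if (!is.null(strand_prob)) {
    p <- c(strand_prob[1L], strand_prob[2L], 1 - sum(strand_prob[1:2]))
    out$strand <- sample(c("+", "-", "."), n, replace = TRUE, prob = p)
  }
  if (sorted) out <- bf_sort(out, cols = cols)
  out
}

check_oracle_size <- function(..., coord_max = 1e6, n_max = 1000) {
  dfs <- list(...)
  for (df in dfs) {
    if (nrow(df) > n_max) {
      rlang::abort(sprintf("oracle instance too large (> %d rows).", n_max),
                   class = "bf_error_oracle")
    }
  }
  invisible(TRUE)
}

#' Brute-force overlap oracle
#'
#' All-pairs double loop with the half-open test, restricted to pairs on the
#' same chromosome. Independent of the sorted/bisection engine; guarded to
#' small instances (at most 1000 rows per table, coordinates at most 1e6) to
#' prevent accidental huge allocations.
#'
#' @inheritParams bf_overlap
#' @return A tibble with integer columns `id_a`, `id_b` (row numbers),
#'   ordered by `(id_a, id_b)`.
#' @export
oracle_overlap <- function(left, right, cols = NULL) {
  cols <- resolve_cols(cols)
  check_oracle_size(left, right)
  check_oracle_coords(left, cols)
  check_oracle_coords(right, cols)
  # every (i, j) combination is materialised and tested — no sorting, no
  # bisection, nothing shared with the engine
  n1 <- nrow(left)
  n2 <- nrow(right)
  i <- rep(seq_len(n1), each = n2)
  j <- rep(seq_len(n2), times = n1)
  ci <- left[[cols[1L]]][i]; si <- left[[cols[2L]]][i]; ei <- left[[cols[3L]]][i]
  cj <- right[[cols[1L]]][j]; sj <- right[[cols[2L]]][j]; ej <- right[[cols[3L]]][j]
  hit <- !is.na(ci) & !is.na(cj) & !is.na(si) & !is.na(ei) &
    !is.na(sj) & !is.na(ej) & ci == cj & si < ej & sj < ei
  tibble::tibble(id_a = i[hit], id_b = j[hit])
}

check_oracle_coords <- function(df, cols, coord_max = 1e6) {
  e <- df[[cols[3L]]]
  if (length(e) && any(!is.na(e) & e > coord_max)) {
    rlang::abort(sprintf("oracle instance coordinates exceed %g.", coord_max),
                 class = "bf_error_oracle")
  }
  invisible(TRUE)
}

#' Per-base bitmap union oracle
#'
#' Counts the bases of `[bounds[1], bounds[2])` covered by at least one
#' interval of the table, by materialising one boolean per base and per
#' chromosome. Multiple chromosomes are summed, each against the same
#' bounds. Guarded to small instances.
#'
#' @inheritParams bf_cluster
#' @param bounds Length-2 integer vector (half-open bounds; at most 1e6
#'   bases).
#' @return A single integer: the number of covered bases.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L))
#' oracle_union_bases(x, c(0, 100))  # 20
#' @export
oracle_union_bases <- function(df, bounds, cols = NULL) {
  cols <- resolve_cols(cols)
  check_oracle_size(df)
  width <- bounds[2L] - bounds[1L]
  if (width > 1e6) {
    rlang::abort("oracle bounds exceed 1e6 bases.", class = "bf_error_oracle")
  }
  if (width <= 0) return(0L)
  total <- 0L
  chroms <- unique(df[[cols[1L]]])
  chroms <- chroms[!is.na(chroms)]
  for (chr in chroms) {
    bitmap <- logical(width)
    ii <- which(df[[cols[1L]]] == chr &
                  !is.na(df[[cols[2L]]]) & !is.na(df[[cols[3L]]]))
    for (i in ii) {
      s <- max(df[[cols[2L]]][i], bounds[1L]) - bounds[1L]
      e <- min(df[[cols[3L]]][i], bounds[2L]) - bounds[1L]
      if (e > s) bitmap[(s + 1L):e] <- TRUE
    }
    total <- total + sum(bitmap)
  }
  as.integer(total)
}

#' Benchmark overlap-join scaling
#'
#' For each size `n`, generates two seeded random tables of `n` intervals,
#' times the inner overlap join, and records the pair count. The per-size
#' seed is `seed * 100 + i` (i the size's position), so each input table can
#' be regenerated independently. `glance()` reports the log-log growth
#' exponent of elapsed time versus `n`; on uniform random input an exponent
#' well below quadratic (< 1.6) is expected from the sort/bisection design.
#'
#' @param sizes Ascending integer vector of table sizes.
#' @param seed Integer seed.
#' @param chromsizes,length_range Passed to [random_intervals()].
#' @param path Optional file path: the report is also written as
#'   tab-separated text.
#' @return A tibble of class `bf_benchmark` with columns `n`, `elapsed`
#'   (seconds) and `pair_count`.
#' @seealso [tidy.bf_benchmark()], [glance.bf_benchmark()],
#'   [autoplot.bf_benchmark()]
#' @export
scaling_benchmark <- function(sizes, seed = 0,
                              chromsizes = c(chr1 = 250e6, chr2 = 200e6,
                                             chr3 = 150e6),
                              length_range = c(1, 10000), path = NULL) {
  if (is.unsorted(sizes, strictly = TRUE)) {
    rlang::abort("`sizes` must be ascending.", class = "bf_error_validation")
  }
  elapsed <- numeric(length(sizes))
  pairs <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    a <- random_intervals(sizes[i], chromsizes, length_range,
                          seed = seed * 100 + 2L * i)
    b <- random_intervals(sizes[i], chromsizes, length_range,
                          seed = seed * 100 + 2L * i + 1L)
    elapsed[i] <- system.time(res <- bf_overlap(a, b, how = "inner"))[["elapsed"]]
    pairs[i] <- nrow(res)
  }
  out <- tibble::tibble(n = as.integer(sizes), elapsed = elapsed,
                        pair_count = pairs)
  class(out) <- c("bf_benchmark", class(out))
  attr(out, "seed") <- seed
  if (!is.null(path)) {
    readr::write_tsv(tibble::as_tibble(unclass(out)), path)
  }
  out
}

#' Tidy a scaling benchmark
#'
#' @param x A `bf_benchmark` object.
#' @param ... Unused.
#' @return `tidy()`: the per-size measurements as a plain tibble.
#'   `glance()`: a one-row tibble with `slope` (log-log growth exponent of
#'   elapsed versus n), `r_squared` and `n_sizes`.
#' @export
tidy.bf_benchmark <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.bf_benchmark
#' @export
glance.bf_benchmark <- function(x, ...) {
  fit <- stats::lm(log(pmax(elapsed, 1e-4)) ~ log(n), data = x)
  tibble::tibble(slope = unname(stats::coef(fit)[2L]),
                 r_squared = summary(fit)$r.squared,
                 n_sizes = nrow(x))
}

#' Plot a scaling benchmark
#'
#' Log-log plot of elapsed time against input size.
#'
#' @param object A `bf_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bf_benchmark <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$n, y = pmax(.data$elapsed, 1e-4))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "intervals per table", y = "elapsed (s)",
                  title = "Overlap join scaling") +
    ggplot2::theme_minimal()
}

#' Plot intervals along a chromosome
#'
#' Simple occupancy plot: each interval drawn as a horizontal segment,
#' stacked by row order and facetted by chromosome.
#'
#' @inheritParams bf_cluster
#' @param colour_by Optional column name mapped to segment colour.
#' @return A ggplot object.
#' @export
plot_intervals <- function(df, colour_by = NULL, cols = NULL) {
  cols <- resolve_cols(cols)
  assert_bedframe(df, cols)
  df <- tibble::as_tibble(df)
  df$.row <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df,
                       ggplot2::aes(x = .data[[cols[2L]]],
                                    xend = .data[[cols[3L]]],
                                    y = .data$.row, yend = .data$.row)) +
    ggplot2::facet_wrap(stats::as.formula(paste("~", cols[1L])),
                        scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(colour_by)) {
    p + ggplot2::geom_segment(ggplot2::aes(colour = .data[[colour_by]]),
                              linewidth = 2)
  } else {
    p + ggplot2::geom_segment(linewidth = 2)
  }
}
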