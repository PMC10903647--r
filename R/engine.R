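# Array-level interval kernels.
#
# Pure functions on plain integer vectors; one call operates on one partition
# (one chromosome x one combination of grouping values), so the kernels never
# see chromosome names or missing values — partitioning and NA filtering
# happen in the user-facing operations. All coordinates are 0-based,
# half-open [start, end): intervals overlap iff start_i < end_j AND
# start_j < end_i, so bookended intervals (end_i == start_j) do not overlap,
# and a zero-length interval overlaps only intervals it lies strictly inside.
#
# Overlaps and neighbours are located by sorting coordinate vectors and
# bisection search (findInterval), never by all-pairs comparison:
# O((n+m)·log(n+m) + k) where k is the output size.

check_interval_vectors <- function(starts, ends, what = "intervals") {
  if (length(starts) != length(ends)) {
    rlang::abort(sprintf("%s: starts and ends must have equal length.", what),
                 class = "bf_error_engine")
  }
  if (anyNA(starts) || anyNA(ends)) {
    rlang::abort(sprintf("%s: missing coordinates must be filtered before the kernel.", what),
                 class = "bf_error_engine")
  }
  if (any(starts > ends)) {
    rlang::abort(sprintf("%s: found start > end.", what), class = "bf_error_engine")
  }
  invisible(TRUE)
}

#' Enumerate overlapping interval pairs by sorted bisection
#'
#' Low-level kernel: given two sets of half-open intervals as parallel
#' start/end vectors, returns every index pair `(id_a, id_b)` with
#' `starts_a[id_a] < ends_b[id_b]` and `starts_b[id_b] < ends_a[id_a]`.
#' Both sets are sorted internally and partner ranges are located by
#' bisection, so the cost is `O((n+m)log(n+m) + k)` for `k` output pairs.
#'
#' @param starts_a,ends_a,starts_b,ends_b Integer vectors of interval
#'   coordinates (0-based, half-open); no missing values.
#' @return A tibble with integer columns `id_a`, `id_b` (1-based positions in
#'   the input vectors), ordered by `(id_a, id_b)`.
#' @examples
#' ivl_overlap_pairs(0L, 10L, 5L, 15L)   # one pair
#' ivl_overlap_pairs(0L, 10L, 10L, 20L)  # bookended: empty
#' @export
ivl_overlap_pairs <- function(starts_a, ends_a, starts_b, ends_b) {
  check_interval_vectors(starts_a, ends_a, "set A")
  check_interval_vectors(starts_b, ends_b, "set B")
  n1 <- length(starts_a)
  n2 <- length(starts_b)
  if (n1 == 0L || n2 == 0L) {
    return(tibble::tibble(id_a = integer(), id_b = integer()))
  }
  o1 <- order(starts_a, ends_a, method = "radix")
  o2 <- order(starts_b, ends_b, method = "radix")
  s1 <- starts_a[o1]; e1 <- ends_a[o1]
  s2 <- starts_b[o2]; e2 <- ends_b[o2]

  # Split pairs by which interval starts first.
  # (A) partners of a-interval i whose start lies in [s1_i, e1_i)
  loA <- findInterval(s1, s2, left.open = TRUE)   # count of s2 <  s1_i
  hiA <- findInterval(e1, s2, left.open = TRUE)   # count of s2 <  e1_i
  cntA <- hiA - loA
  ia <- rep.int(o1, cntA)
  ib <- o2[sequence(cntA, from = loA + 1L)]
  # a zero-length b at exactly s1 slips into the range but does not overlap
  keep <- ends_b[ib] > starts_a[ia]
  ia <- ia[keep]; ib <- ib[keep]
  # (B) partners of b-interval j whose start lies strictly inside (s2_j, e2_j)
  loB <- findInterval(s2, s1)                     # count of s1 <= s2_j
  hiB <- findInterval(e2, s1, left.open = TRUE)   # count of s1 <  e2_j
  cntB <- pmax(hiB - loB, 0L)
  ja <- o1[sequence(cntB, from = loB + 1L)]
  jb <- rep.int(o2, cntB)

  id_a <- c(ia, ja)
  id_b <- c(ib, jb)
  ord <- order(id_a, id_b, method = "radix")
  tibble::tibble(id_a = id_a[ord], id_b = id_b[ord])
}

#' Sweep-line clustering of intervals
#'
#' Single left-to-right sweep over intervals sorted by `(start, end)`. A new
#' run opens when the gap between the next start and the running maximum end
#' exceeds the joining rule: with `min_dist = NULL` only strictly overlapping
#' intervals join (`next start < running end` required); with
#' `min_dist = d >= 0` intervals join when `next start - running end <= d`,
#' so bookended intervals join at `d = 0`.
#'
#' @param starts,ends Interval coordinates (no missing values).
#' @param min_dist `NULL` for strict overlap, or a non-negative maximum gap.
#' @return A list with `cluster` (dense 1-based run id per input interval, in
#'   input order, numbered by run start), `run_start`, `run_end` and `run_n`
#'   (per-run span and member count; runs are sorted and non-overlapping).
#' @examples
#' ivl_cluster(c(0L, 10L), c(10L, 20L), min_dist = 0L)$cluster  # 1 1
#' ivl_cluster(c(0L, 10L), c(10L, 20L), min_dist = NULL)$cluster  # 1 2
#' @export
ivl_cluster <- function(starts, ends, min_dist = NULL) {
  check_interval_vectors(starts, ends)
  if (!is.null(min_dist)) {
    if (!is.numeric(min_dist) || length(min_dist) != 1L || is.na(min_dist) ||
        min_dist < 0) {
      rlang::abort("`min_dist` must be NULL or a single non-negative number.",
                   class = "bf_error_engine")
    }
  }
  n <- length(starts)
  if (n == 0L) {
    return(list(cluster = integer(), run_start = integer(),
                run_end = integer(), run_n = integer()))
  }
  ord <- order(starts, ends, method = "radix")
  s <- starts[ord]
  e <- ends[ord]
  cmax <- cummax(e)
  prev_max <- c(NA, cmax[-n])
  new_run <- if (is.null(min_dist)) {
    s >= prev_max              # join requires next start < running end
  } else {
    (s - prev_max) > min_dist  # join when gap <= min_dist
  }
  new_run[1L] <- TRUE
  cid <- cumsum(new_run)
  cluster <- integer(n)
  cluster[ord] <- cid
  last_idx <- c(which(new_run)[-1L] - 1L, n)
  list(cluster = cluster,
       run_start = s[new_run],
       run_end = cmax[last_idx],
       run_n = tabulate(cid))
}

#' Complement of an interval set within bounds
#'
#' Returns the maximal sub-intervals of `[bounds_start, bounds_end)` covered
#' by no input interval. Inputs are clipped to the bounds first; intervals
#' entirely outside are ignored.
#'
#' @inheritParams ivl_cluster
#' @param bounds_start,bounds_end Single integers, `bounds_start <= bounds_end`.
#' @return A tibble with columns `start`, `end`: sorted, non-overlapping,
#'   non-empty gap runs.
#' @examples
#' ivl_complement(10L, 20L, 0L, 30L)
#' @export
ivl_complement <- function(starts, ends, bounds_start, bounds_end) {
  check_interval_vectors(starts, ends)
  if (bounds_start > bounds_end) {
    rlang::abort("complement bounds must satisfy start <= end.",
                 class = "bf_error_engine")
  }
  s <- pmax(starts, bounds_start)
  e <- pmin(ends, bounds_end)
  keep <- s < e  # zero-length (incl. fully clipped) covers nothing
  s <- s[keep]
  e <- e[keep]
  if (length(s) == 0L) {
    if (bounds_start < bounds_end) {
      return(tibble::tibble(start = bounds_start, end = bounds_end))
    }
    return(tibble::tibble(start = integer(), end = integer()))
  }
  runs <- ivl_cluster(s, e, min_dist = 0L)
  gap_start <- c(bounds_start, runs$run_end)
  gap_end <- c(runs$run_start, bounds_end)
  keep <- gap_start < gap_end
  tibble::tibble(start = gap_start[keep], end = gap_end[keep])
}

#' k-nearest interval neighbours by bisection
#'
#' For each interval of set A, finds up to `k` partners in set B minimising
#' distance, where overlapping pairs have distance 0 and non-overlapping
#' pairs the gap between their nearest ends. A partner is *upstream* when it
#' lies entirely at lower coordinates (`end_b <= start_a`) and *downstream*
#' when entirely at higher coordinates (`start_b >= end_a`); direction is
#' purely coordinate-based (strand-aware behaviour is composed by the
#' caller). Candidates are located by bisection into B sorted by start and by
#' end, scanning outward, never by all-pairs comparison.
#'
#' Ties in distance are broken by smaller partner start, then smaller
#' partner index.
#'
#' @inheritParams ivl_overlap_pairs
#' @param k Number of neighbours per query (`k >= 1`).
#' @param include_overlaps If `FALSE`, partners overlapping the query
#'   (distance 0 by overlap) are excluded; bookended partners (distance 0
#'   without overlap) are always eligible.
#' @param include_upstream,include_downstream Direction filters.
#' @param self Set `TRUE` when A and B are the same set, to exclude the
#'   pairing of an interval with itself (same index).
#' @return A tibble with integer columns `id_a`, `id_b` and numeric
#'   `distance`, ordered by `(id_a, distance, partner start, id_b)`.
#' @examples
#' ivl_nearest(0L, 10L, c(20L, 40L), c(30L, 50L), k = 1)  # distance 10
#' @export
ivl_nearest <- function(starts_a, ends_a, starts_b, ends_b, k = 1L,
                        include_overlaps = TRUE,
                        include_upstream = TRUE,
                        include_downstream = TRUE,
                        self = FALSE) {
  check_interval_vectors(starts_a, ends_a, "set A")
  check_interval_vectors(starts_b, ends_b, "set B")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    rlang::abort("`k` must be a single integer >= 1.", class = "bf_error_engine")
  }
  k <- as.integer(k)
  n1 <- length(starts_a)
  n2 <- length(starts_b)
  empty <- tibble::tibble(id_a = integer(), id_b = integer(),
                          distance = numeric())
  if (n1 == 0L || n2 == 0L) return(empty)

  ov_by_query <- NULL
  if (include_overlaps) {
    ov <- ivl_overlap_pairs(starts_a, ends_a, starts_b, ends_b)
    if (self) ov <- ov[ov$id_a != ov$id_b, ]
    ov_by_query <- split(ov$id_b, factor(ov$id_a, levels = seq_len(n1)))
  }
  o_end <- order(ends_b, starts_b, method = "radix")
  eb <- ends_b[o_end]
  o_start <- order(starts_b, ends_b, method = "radix")
  sb <- starts_b[o_start]

  out_a <- vector("list", n1)
  out_b <- vector("list", n1)
  out_d <- vector("list", n1)
  for (i in seq_len(n1)) {
    cand_id <- integer(0)
    cand_d <- numeric(0)
    if (include_overlaps) {
      ids <- ov_by_query[[i]]
      if (length(ids)) {
        cand_id <- ids
        cand_d <- numeric(length(ids))
      }
    }
    if (include_upstream) {
      # bisect to the rightmost fully-upstream partner, then scan outward
      # (non-decreasing gap) until k found plus any ties at the k-th gap
      p <- findInterval(starts_a[i], eb)  # count of ends_b <= start_a
      ids <- integer(0)
      gaps <- numeric(0)
      j <- p
      while (j >= 1L) {
        id <- o_end[j]
        if (!(self && id == i)) {
          g <- starts_a[i] - eb[j]
          if (length(ids) >= k && g > gaps[k]) break
          ids <- c(ids, id)
          gaps <- c(gaps, g)
        }
        j <- j - 1L
      }
      cand_id <- c(cand_id, ids)
      cand_d <- c(cand_d, gaps)
    }
    if (include_downstream) {
      q <- findInterval(ends_a[i], sb, left.open = TRUE)  # count of starts_b < end_a
      ids <- integer(0)
      gaps <- numeric(0)
      j <- q + 1L
      while (j <= n2) {
        id <- o_start[j]
        if (!(self && id == i)) {
          g <- sb[j] - ends_a[i]
          if (length(ids) >= k && g > gaps[k]) break
          ids <- c(ids, id)
          gaps <- c(gaps, g)
        }
        j <- j + 1L
      }
      cand_id <- c(cand_id, ids)
      cand_d <- c(cand_d, gaps)
    }
    if (!length(cand_id)) next
    # a partner can qualify both upstream and downstream (zero-length edge
    # cases): keep one entry per partner with the smaller distance
    if (anyDuplicated(cand_id)) {
      o <- order(cand_id, cand_d, method = "radix")
      cand_id <- cand_id[o]; cand_d <- cand_d[o]
      keep <- !duplicated(cand_id)
      cand_id <- cand_id[keep]; cand_d <- cand_d[keep]
    }
    rk <- order(cand_d, starts_b[cand_id], cand_id, method = "radix")
    rk <- rk[seq_len(min(k, length(rk)))]
    out_a[[i]] <- rep.int(i, length(rk))
    out_b[[i]] <- cand_id[rk]
    out_d[[i]] <- cand_d[rk]
  }
  tibble::tibble(id_a = unlist(out_a) %||% integer(),
                 id_b = as.integer(unlist(out_b) %||% integer()),
                 distance = as.numeric(unlist(out_d) %||% numeric()))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
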