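# User-facing interval operations on bedframes.
#
# Every operation partitions its input(s) by chromosome plus any extra
# grouping columns (`on`), runs an engine kernel per partition on the rows
# with complete coordinates, and reassembles a tibble that carries every
# annotation column of the input(s) unchanged. Rows with missing coordinates
# are excluded from geometry; join-style operations reattach them as
# unmatched rows under the `left`/`outer` modes.

check_on <- function(on, left, right = NULL) {
  if (is.null(on) || length(on) == 0L) return(character(0))
  if (!is.character(on)) {
    rlang::abort("`on` must be a character vector of column names.",
                 class = "bf_error_validation")
  }
  miss <- setdiff(on, names(left))
  if (length(miss)) {
    rlang::abort(sprintf("`on` column(s) %s absent from the left table.",
                         paste0("'", miss, "'", collapse = ", ")),
                 class = "bf_error_validation")
  }
  if (!is.null(right)) {
    miss <- setdiff(on, names(right))
    if (length(miss)) {
      rlang::abort(sprintf("`on` column(s) %s absent from the right table.",
                           paste0("'", miss, "'", collapse = ", ")),
                   class = "bf_error_validation")
    }
  }
  on
}

# Partition keys (chrom + on) for the complete-coordinate rows of a table.
partition_keys <- function(df, rows, cols, on) {
  keys <- df[rows, c(cols[1L], on), drop = FALSE]
  names(keys)[1L] <- ".bf_chrom"
  keys <- tibble::as_tibble(keys)
  keys$.bf_chrom <- as.character(keys$.bf_chrom)
  keys
}

# For each partition shared by both tables, row indices (original numbering).
shared_partitions <- function(left, right, cols, cols_r, on) {
  okl <- which(complete_coord_rows(left, cols))
  okr <- which(complete_coord_rows(right, cols_r))
  keys_l <- partition_keys(left, okl, cols, on)
  keys_r <- partition_keys(right, okr, cols_r, on)
  uk <- vctrs::vec_unique(vctrs::vec_rbind(keys_l, keys_r))
  gl <- vctrs::vec_match(keys_l, uk)
  gr <- vctrs::vec_match(keys_r, uk)
  groups_l <- split(okl, gl)
  groups_r <- split(okr, gr)
  list(left = groups_l, right = groups_r,
       common = intersect(names(groups_l), names(groups_r)),
       okl = okl, okr = okr)
}

apply_suffix <- function(nms, suffix) {
  if (nzchar(suffix)) paste0(nms, suffix) else nms
}

check_suffixes <- function(suffixes) {
  if (!is.character(suffixes) || length(suffixes) != 2L || anyNA(suffixes)) {
    rlang::abort("`suffixes` must be two character values.",
                 class = "bf_error_validation")
  }
  suffixes
}

# Assemble a pair table: left rows li against right rows ri (NA = unmatched).
bind_pair_table <- function(left, right, li, ri, suffixes, extra = NULL) {
  lnames <- apply_suffix(names(left), suffixes[1L])
  rnames <- apply_suffix(names(right), suffixes[2L])
  all_names <- c(lnames, rnames, names(extra))
  if (anyDuplicated(all_names)) {
    dup <- unique(all_names[duplicated(all_names)])
    rlang::abort(sprintf("suffixes produce duplicate column name(s): %s.",
                         paste0("'", dup, "'", collapse = ", ")),
                 class = "bf_error_validation")
  }
  lo <- vctrs::vec_slice(tibble::as_tibble(left), li)
  ro <- vctrs::vec_slice(tibble::as_tibble(right), ri)
  names(lo) <- lnames
  names(ro) <- rnames
  out <- vctrs::vec_cbind(lo, ro)
  if (!is.null(extra)) out <- vctrs::vec_cbind(out, tibble::as_tibble(extra))
  out
}

#' Overlap join between two interval tables
#'
#' Finds pairs of intervals from `left` and `right` that overlap under
#' half-open semantics, partitioning by chromosome plus any extra grouping
#' columns in `on` (for example `"strand"`). All annotation columns of both
#' inputs are preserved; right-side columns are disambiguated with
#' `suffixes`.
#'
#' @param left,right Bedframes (data frames with the coordinate triple).
#' @param how Join mode: `"inner"` keeps only genuinely overlapping pairs;
#'   `"left"`/`"right"` additionally keep unmatched rows of that side with
#'   missing values opposite; `"outer"` keeps unmatched rows of both sides.
#'   Rows with missing coordinates take part as unmatched rows in
#'   `left`/`right`/`outer` modes.
#' @param on Extra grouping columns present in both tables; pairs are only
#'   formed within identical values.
#' @param suffixes Length-2 character: appended to left and right column
#'   names. Collisions raise an error rather than silently renaming.
#' @param return_overlap Add `overlap_start`, `overlap_end`,
#'   `overlap_length` columns for the intersection geometry.
#' @param return_index Add `index`/`index_`-style columns with the original
#'   row numbers of each side (suffixes applied).
#' @param cols,cols_right Coordinate column triples for `left` and `right`
#'   (default: the configuration in force, see [bf_cols()]).
#' @return A tibble; matched rows ordered by (left row, right row), then any
#'   unmatched right rows.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
#' b <- tibble::tibble(chrom = "chr1", start = 5L, end = 15L)
#' bf_overlap(a, b, return_overlap = TRUE)
#' @export
bf_overlap <- function(left, right, how = c("inner", "left", "right", "outer"),
                       on = NULL, suffixes = c("", "_"),
                       return_overlap = FALSE, return_index = FALSE,
                       cols = NULL, cols_right = cols) {
  how <- match.arg(how)
  cols <- resolve_cols(cols)
  cols_r <- resolve_cols(cols_right)
  suffixes <- check_suffixes(suffixes)
  assert_bedframe(left, cols, df_name = "left")
  assert_bedframe(right, cols_r, df_name = "right")
  on <- check_on(on, left, right)
  left <- tibble::as_tibble(left)
  right <- tibble::as_tibble(right)

  parts <- shared_partitions(left, right, cols, cols_r, on)
  sl <- left[[cols[2L]]]; el <- left[[cols[3L]]]
  sr <- right[[cols_r[2L]]]; er <- right[[cols_r[3L]]]
  li <- integer(0); ri <- integer(0)
  for (g in parts$common) {
    ii <- parts$left[[g]]
    jj <- parts$right[[g]]
    prs <- ivl_overlap_pairs(sl[ii], el[ii], sr[jj], er[jj])
    li <- c(li, ii[prs$id_a])
    ri <- c(ri, jj[prs$id_b])
  }
  if (how %in% c("left", "outer")) {
    un_l <- setdiff(seq_len(nrow(left)), li)
    li <- c(li, un_l)
    ri <- c(ri, rep(NA_integer_, length(un_l)))
  }
  ord <- order(li, ri, method = "radix", na.last = TRUE)
  li <- li[ord]; ri <- ri[ord]
  if (how %in% c("right", "outer")) {
    un_r <- setdiff(seq_len(nrow(right)), ri)
    li <- c(li, rep(NA_integer_, length(un_r)))
    ri <- c(ri, un_r)
  }

  extra <- NULL
  if (return_overlap) {
    os <- pmax(sl[li], sr[ri])
    oe <- pmin(el[li], er[ri])
    extra <- tibble::tibble(overlap_start = os, overlap_end = oe,
                            overlap_length = oe - os)
  }
  if (return_index) {
    idx <- tibble::tibble(li, ri)
    names(idx) <- c(apply_suffix("index", suffixes[1L]),
                    apply_suffix("index", suffixes[2L]))
    extra <- if (is.null(extra)) idx else vctrs::vec_cbind(idx, extra)
  }
  bind_pair_table(left, right, li, ri, suffixes, extra)
}

#' Cluster intervals by proximity
#'
#' Annotates each row with a dense cluster id: two intervals share an id iff
#' they are transitively connected under the joining rule within their
#' partition (chromosome plus `on` columns). With `min_dist = NULL` only
#' strictly overlapping intervals join; with `min_dist = d >= 0` intervals
#' with gap at most `d` join (bookended intervals join at `d = 0`). Ids are
#' numbered from 1 in order of cluster start within lexicographic partition
#' order; `cluster_start`/`cluster_end` give each cluster's span. Rows with
#' missing coordinates get missing cluster columns.
#'
#' @inheritParams bf_overlap
#' @param df A bedframe.
#' @param min_dist `NULL` (strict overlap) or a non-negative maximum gap.
#' @return The input tibble plus `cluster`, `cluster_start`, `cluster_end`.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(0L, 5L, 30L),
#'                     end = c(10L, 20L, 40L))
#' bf_cluster(x, min_dist = 0)$cluster
#' @export
bf_cluster <- function(df, min_dist = 0, on = NULL, cols = NULL) {
  cols <- resolve_cols(cols)
  assert_bedframe(df, cols)
  on <- check_on(on, df)
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  ok <- which(complete_coord_rows(df, cols))
  cluster <- rep(NA_integer_, n)
  cstart <- rep(NA_integer_, n)
  cend <- rep(NA_integer_, n)
  if (length(ok)) {
    keys <- partition_keys(df, ok, cols, on)
    uk <- vctrs::vec_unique(keys)
    uk <- vctrs::vec_slice(uk, vctrs::vec_order(uk))  # lexicographic partitions
    gid <- vctrs::vec_match(keys, uk)
    s <- df[[cols[2L]]]; e <- df[[cols[3L]]]
    offset <- 0L
    for (g in seq_len(nrow(uk))) {
      ii <- ok[gid == g]
      res <- ivl_cluster(s[ii], e[ii], min_dist = min_dist)
      cluster[ii] <- res$cluster + offset
      cstart[ii] <- res$run_start[res$cluster]
      cend[ii] <- res$run_end[res$cluster]
      offset <- offset + length(res$run_n)
    }
  }
  df$cluster <- cluster
  df$cluster_start <- cstart
  df$cluster_end <- cend
  df
}

#' Merge intervals into maximal runs
#'
#' One output row per cluster (see [bf_cluster()] for the joining rule):
#' chromosome, cluster span, the partition's `on` values and the member
#' count `n_intervals`. Output is sorted and non-overlapping within each
#' partition; merging is idempotent. Rows with missing coordinates are
#' excluded.
#'
#' @inheritParams bf_cluster
#' @return A tibble with the coordinate triple, `on` columns and
#'   `n_intervals`.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(0L, 5L), end = c(10L, 20L))
#' bf_merge(x)
#' @export
bf_merge <- function(df, min_dist = 0, on = NULL, cols = NULL) {
  cols <- resolve_cols(cols)
  assert_bedframe(df, cols)
  on <- check_on(on, df)
  df <- tibble::as_tibble(df)
  ok <- which(complete_coord_rows(df, cols))
  keys <- partition_keys(df, ok, cols, on)
  uk <- vctrs::vec_unique(keys)
  uk <- vctrs::vec_slice(uk, vctrs::vec_order(uk))
  gid <- vctrs::vec_match(keys, uk)
  s <- df[[cols[2L]]]; e <- df[[cols[3L]]]
  pieces <- vector("list", nrow(uk))
  for (g in seq_len(nrow(uk))) {
    ii <- ok[gid == g]
    res <- ivl_cluster(s[ii], e[ii], min_dist = min_dist)
    key_row <- vctrs::vec_slice(uk, g)
    part <- tibble::tibble(!!cols[1L] := key_row$.bf_chrom,
                           !!cols[2L] := res$run_start,
                           !!cols[3L] := res$run_end)
    for (oc in on) part[[oc]] <- vctrs::vec_recycle(key_row[[oc]], nrow(part))
    part$n_intervals <- res$run_n
    pieces[[g]] <- part
  }
  out <- if (length(pieces)) vctrs::vec_rbind(!!!pieces) else
    tibble::tibble(!!cols[1L] := character(), !!cols[2L] := integer(),
                   !!cols[3L] := integer(), n_intervals = integer())
  tibble::as_tibble(out)
}

#' Nearest features between two interval tables
#'
#' For each row of `left`, up to `k` nearest rows of `right` and the genomic
#' distance between them: 0 for overlapping pairs, otherwise the gap between
#' nearest ends. Upstream/downstream are purely coordinate-based (a partner
#' is upstream when entirely at lower coordinates); strand-aware behaviour is
#' composed by the caller flipping the direction flags per strand. Left rows
#' with no eligible partner appear once with missing right columns and
#' missing distance. Ties are broken by (distance, partner start, partner
#' row).
#'
#' @inheritParams bf_overlap
#' @param right A bedframe, or `NULL` for self mode: partners are drawn from
#'   `left` itself and the pairing of a row with itself is excluded.
#' @param k Number of nearest partners per left row.
#' @param ignore_overlaps Exclude partners overlapping the query (distance 0
#'   by overlap); bookended partners remain eligible.
#' @param ignore_upstream,ignore_downstream Exclude partners entirely at
#'   lower / higher coordinates.
#' @return A tibble: left columns, right columns (suffixed), `distance`.
#' @examples
#' g <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
#' p <- tibble::tibble(chrom = "chr1", start = c(0L, 300L), end = c(50L, 400L))
#' bf_closest(g, p)$distance  # 50
#' @export
bf_closest <- function(left, right = NULL, k = 1L,
                       ignore_overlaps = FALSE, ignore_upstream = FALSE,
                       ignore_downstream = FALSE, on = NULL,
                       suffixes = c("", "_"), cols = NULL, cols_right = cols) {
  cols <- resolve_cols(cols)
  cols_r <- resolve_cols(cols_right)
  suffixes <- check_suffixes(suffixes)
  self <- is.null(right)
  if (self) {
    right <- left
    cols_r <- cols
  }
  assert_bedframe(left, cols, df_name = "left")
  assert_bedframe(right, cols_r, df_name = "right")
  on <- check_on(on, left, right)
  left <- tibble::as_tibble(left)
  right <- tibble::as_tibble(right)

  parts <- shared_partitions(left, right, cols, cols_r, on)
  sl <- left[[cols[2L]]]; el <- left[[cols[3L]]]
  sr <- right[[cols_r[2L]]]; er <- right[[cols_r[3L]]]
  li <- integer(0); ri <- integer(0); dist <- numeric(0)
  for (g in parts$common) {
    ii <- parts$left[[g]]
    jj <- parts$right[[g]]  # self mode: same table, so jj == ii
    res <- ivl_nearest(sl[ii], el[ii], sr[jj], er[jj], k = k,
                       include_overlaps = !ignore_overlaps,
                       include_upstream = !ignore_upstream,
                       include_downstream = !ignore_downstream,
                       self = self)
    li <- c(li, ii[res$id_a])
    ri <- c(ri, jj[res$id_b])
    dist <- c(dist, res$distance)
  }
  un_l <- setdiff(seq_len(nrow(left)), li)
  li <- c(li, un_l)
  ri <- c(ri, rep(NA_integer_, length(un_l)))
  dist <- c(dist, rep(NA_real_, length(un_l)))
  ord <- order(li, method = "radix")  # stable: keeps per-query rank order
  bind_pair_table(left, right, li[ord], ri[ord], suffixes,
                  extra = tibble::tibble(distance = dist[ord]))
}

#' Complement of an interval table within a genomic view
#'
#' Per view region, the maximal gaps not covered by any interval of the
#' table on that region's chromosome (intervals are clipped to the region).
#' The output is cataloged — each gap labelled with its region's name in the
#' `view_region` column — and sorted in view order. Intervals on
#' chromosomes absent from the view are ignored; their count is attached as
#' the `bf_ignored` attribute.
#'
#' @inheritParams bf_cluster
#' @param view A genomic view (see [is_viewframe()]).
#' @param name_col Region-name column of the view.
#' @return A tibble with the coordinate triple and `view_region`.
#' @examples
#' v <- bf_make_view(c(chr1 = 100))
#' bf_complement(tibble::tibble(chrom = "chr1", start = 20L, end = 30L), v)
#' @export
bf_complement <- function(df, view, cols = NULL, name_col = NULL) {
  cols <- resolve_cols(cols)
  name_col <- bf_name_col(name_col)
  assert_bedframe(df, cols)
  assert_viewframe(view, cols, name_col)
  df <- tibble::as_tibble(df)
  ok <- which(complete_coord_rows(df, cols))
  chrom <- as.character(df[[cols[1L]]])
  s <- df[[cols[2L]]]; e <- df[[cols[3L]]]
  vchrom <- as.character(view[[cols[1L]]])
  pieces <- vector("list", nrow(view))
  for (r in seq_len(nrow(view))) {
    ii <- ok[chrom[ok] == vchrom[r]]
    gaps <- ivl_complement(s[ii], e[ii],
                           view[[cols[2L]]][r], view[[cols[3L]]][r])
    if (nrow(gaps)) {
      pieces[[r]] <- tibble::tibble(!!cols[1L] := vchrom[r],
                                    !!cols[2L] := gaps$start,
                                    !!cols[3L] := gaps$end,
                                    view_region = view[[name_col]][r])
    }
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- if (length(pieces)) tibble::as_tibble(vctrs::vec_rbind(!!!pieces)) else
    tibble::tibble(!!cols[1L] := character(), !!cols[2L] := integer(),
                   !!cols[3L] := integer(), view_region = character())
  attr(out, "bf_ignored") <- sum(!(chrom[ok] %in% vchrom))
  out
}

# merged runs of the complete rows of `right` per (chrom + on) partition;
# returns a function look-up used by coverage/subtract
merged_runs_by_partition <- function(right, okr, cols_r, on, gid_r, n_groups) {
  s <- right[[cols_r[2L]]]; e <- right[[cols_r[3L]]]
  runs <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    jj <- okr[gid_r == g]
    if (!length(jj)) next
    res <- ivl_cluster(s[jj], e[jj], min_dist = NULL)
    runs[[g]] <- list(start = res$run_start, end = res$run_end)
  }
  runs
}

#' Bases of each interval covered by the union of another set
#'
#' Adds a `coverage` column to `left`: the number of its bases covered by
#' the union of `right` intervals (the right set is merged internally, so
#' multiply-covered bases count once); `0 <= coverage <= end - start`. Rows
#' with missing coordinates get missing coverage.
#'
#' @inheritParams bf_overlap
#' @return `left` as a tibble plus a `coverage` column (integer bp).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
#' b <- tibble::tibble(chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L))
#' bf_coverage(a, b)$coverage  # 20
#' @export
bf_coverage <- function(left, right, on = NULL, cols = NULL,
                        cols_right = cols) {
  cols <- resolve_cols(cols)
  cols_r <- resolve_cols(cols_right)
  assert_bedframe(left, cols, df_name = "left")
  assert_bedframe(right, cols_r, df_name = "right")
  on <- check_on(on, left, right)
  left <- tibble::as_tibble(left)
  right <- tibble::as_tibble(right)
  parts <- shared_partitions(left, right, cols, cols_r, on)
  sl <- left[[cols[2L]]]; el <- left[[cols[3L]]]
  cov <- rep(NA_integer_, nrow(left))
  cov[parts$okl] <- 0L
  for (g in parts$common) {
    ii <- parts$left[[g]]
    jj <- parts$right[[g]]
    res <- ivl_cluster(right[[cols_r[2L]]][jj], right[[cols_r[3L]]][jj],
                       min_dist = NULL)
    prs <- ivl_overlap_pairs(sl[ii], el[ii], res$run_start, res$run_end)
    if (nrow(prs)) {
      ov <- pmin(el[ii][prs$id_a], res$run_end[prs$id_b]) -
        pmax(sl[ii][prs$id_a], res$run_start[prs$id_b])
      sums <- rowsum(ov, group = prs$id_a)
      cov[ii[as.integer(rownames(sums))]] <- as.integer(sums[, 1L])
    }
  }
  left$coverage <- cov
  left
}

#' Number of overlapping intervals from another set
#'
#' Adds a `count` column to `left`: how many `right` intervals overlap each
#' left interval (equivalently, the group size per left row of the inner
#' overlap join). Rows with missing coordinates get a missing count.
#'
#' @inheritParams bf_overlap
#' @return `left` as a tibble plus an integer `count` column.
#' @export
bf_count_overlaps <- function(left, right, on = NULL, cols = NULL,
                              cols_right = cols) {
  cols <- resolve_cols(cols)
  cols_r <- resolve_cols(cols_right)
  assert_bedframe(left, cols, df_name = "left")
  assert_bedframe(right, cols_r, df_name = "right")
  on <- check_on(on, left, right)
  left <- tibble::as_tibble(left)
  right <- tibble::as_tibble(right)
  parts <- shared_partitions(left, right, cols, cols_r, on)
  cnt <- rep(NA_integer_, nrow(left))
  cnt[parts$okl] <- 0L
  sl <- left[[cols[2L]]]; el <- left[[cols[3L]]]
  sr <- right[[cols_r[2L]]]; er <- right[[cols_r[3L]]]
  for (g in parts$common) {
    ii <- parts$left[[g]]
    jj <- parts$right[[g]]
    prs <- ivl_overlap_pairs(sl[ii], el[ii], sr[jj], er[jj])
    cnt[ii] <- tabulate(prs$id_a, nbins = length(ii))
  }
  left$count <- cnt
  left
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Resize intervals by padding or scaling
#'
#' With `pad`, subtracts/adds a fixed number of bases on the chosen side(s);
#' a negative pad shrinks, and an interval that would invert collapses to its
#' midpoint `floor((start + end) / 2)`. With `scale`, the new length is
#' `round(scale * length)` (half away from zero) kept centred on the original
#' midpoint. Coordinates may become negative; clipping to a view is a
#' separate, explicit step ([bf_trim()]).
#'
#' @inheritParams bf_cluster
#' @param pad Integer number of bases (may be negative); exactly one of
#'   `pad`/`scale` must be given.
#' @param scale Non-negative length multiplier.
#' @param side `"both"` (default), `"left"` or `"right"`; applies to `pad`.
#' @return The input tibble with resized coordinates.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L)
#' bf_expand(x, pad = 5)[, 2:3]     # 5, 25
#' bf_expand(x, scale = 2)[, 2:3]   # 5, 25
#' @export
bf_expand <- function(df, pad = NULL, scale = NULL,
                      side = c("both", "left", "right"), cols = NULL) {
  side <- match.arg(side)
  cols <- resolve_cols(cols)
  assert_bedframe(df, cols)
  if (is.null(pad) == is.null(scale)) {
    rlang::abort("give exactly one of `pad` or `scale`.",
                 class = "bf_error_validation")
  }
  if (!is.null(scale) && scale < 0) {
    rlang::abort("`scale` must be >= 0.", class = "bf_error_validation")
  }
  df <- tibble::as_tibble(df)
  s <- df[[cols[2L]]]
  e <- df[[cols[3L]]]
  if (!is.null(pad)) {
    ns <- if (side %in% c("both", "left")) s - pad else s
    ne <- if (side %in% c("both", "right")) e + pad else e
    inv <- !is.na(ns) & !is.na(ne) & ns > ne
    mid <- floor((s + e) / 2)
    ns[inv] <- mid[inv]
    ne[inv] <- mid[inv]
  } else {
    len <- round_half_away(scale * (e - s))
    mid <- floor((s + e) / 2)
    ns <- mid - floor(len / 2)
    ne <- ns + len
  }
  df[[cols[2L]]] <- as.integer(ns)
  df[[cols[3L]]] <- as.integer(ne)
  df
}

#' Subtract one interval set from another
#'
#' Splits each `left` interval into the sub-intervals not covered by the
#' union of `right` intervals on the same chromosome; annotation columns are
#' duplicated onto each remnant and fully covered intervals vanish. Rows of
#' `left` with missing coordinates are dropped (counted in the `bf_dropped`
#' attribute).
#'
#' @inheritParams bf_overlap
#' @return A tibble with the columns of `left`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
#' b <- tibble::tibble(chrom = "chr1", start = 40L, end = 60L)
#' bf_subtract(a, b)
#' @export
bf_subtract <- function(left, right, cols = NULL, cols_right = cols) {
  cols <- resolve_cols(cols)
  cols_r <- resolve_cols(cols_right)
  assert_bedframe(left, cols, df_name = "left")
  assert_bedframe(right, cols_r, df_name = "right")
  left <- tibble::as_tibble(left)
  right <- tibble::as_tibble(right)
  parts <- shared_partitions(left, right, cols, cols_r, on = character(0))
  sl <- left[[cols[2L]]]; el <- left[[cols[3L]]]
  keep_idx <- integer(0)   # output: left row index per remnant
  new_s <- integer(0)
  new_e <- integer(0)
  touched <- rep(FALSE, nrow(left))
  for (g in parts$common) {
    ii <- parts$left[[g]]
    jj <- parts$right[[g]]
    res <- ivl_cluster(right[[cols_r[2L]]][jj], right[[cols_r[3L]]][jj],
                       min_dist = NULL)
    rs <- res$run_start; re <- res$run_end
    pos_len <- re > rs  # zero-length runs cover nothing
    prs <- ivl_overlap_pairs(sl[ii], el[ii], rs, re)
    prs <- prs[pos_len[prs$id_b], , drop = FALSE]
    if (!nrow(prs)) next
    by_row <- split(prs$id_b, prs$id_a)
    for (nm in names(by_row)) {
      a <- as.integer(nm)
      row <- ii[a]
      touched[row] <- TRUE
      runs <- sort(by_row[[nm]])
      gs <- c(sl[row], re[runs])
      ge <- c(rs[runs], el[row])
      pos <- gs < ge
      gs <- pmax(gs[pos], sl[row])
      ge <- pmin(ge[pos], el[row])
      if (length(gs)) {
        keep_idx <- c(keep_idx, rep.int(row, length(gs)))
        new_s <- c(new_s, gs)
        new_e <- c(new_e, ge)
      }
    }
  }
  unmatched <- parts$okl[!touched[parts$okl]]
  keep_idx <- c(keep_idx, unmatched)
  new_s <- c(new_s, sl[unmatched])
  new_e <- c(new_e, el[unmatched])
  ord <- order(keep_idx, new_s, method = "radix")
  out <- vctrs::vec_slice(left, keep_idx[ord])
  out[[cols[2L]]] <- as.integer(new_s[ord])
  out[[cols[3L]]] <- as.integer(new_e[ord])
  attr(out, "bf_dropped") <- nrow(left) - length(parts$okl)
  out
}

#' Remove intervals that overlap another set
#'
#' Whole-row removal, no splitting: keeps the rows of `left` having zero
#' overlaps with `right` (equivalently, the rows where [bf_count_overlaps()]
#' is zero). Rows with missing coordinates have no overlaps and are kept.
#'
#' @inheritParams bf_overlap
#' @return A tibble with the non-overlapping subset of `left`'s rows.
#' @export
bf_setdiff <- function(left, right, on = NULL, cols = NULL,
                       cols_right = cols) {
  cols <- resolve_cols(cols)
  cols_r <- resolve_cols(cols_right)
  assert_bedframe(left, cols, df_name = "left")
  assert_bedframe(right, cols_r, df_name = "right")
  on <- check_on(on, left, right)
  left <- tibble::as_tibble(left)
  right <- tibble::as_tibble(right)
  parts <- shared_partitions(left, right, cols, cols_r, on)
  sl <- left[[cols[2L]]]; el <- left[[cols[3L]]]
  sr <- right[[cols_r[2L]]]; er <- right[[cols_r[3L]]]
  hit <- rep(FALSE, nrow(left))
  for (g in parts$common) {
    ii <- parts$left[[g]]
    jj <- parts$right[[g]]
    prs <- ivl_overlap_pairs(sl[ii], el[ii], sr[jj], er[jj])
    hit[ii[unique(prs$id_a)]] <- TRUE
  }
  vctrs::vec_slice(left, !hit)
}

#' Clip intervals to their assigned view regions
#'
#' Each row is assigned to a view region (reusing an existing `view_region`
#' column when present and cataloged, otherwise via [bf_assign_view()]) and
#' clipped to that region's bounds: `start := max(start, region start)`,
#' `end := min(end, region end)`. Rows whose intersection with their region
#' is empty — including rows on chromosomes with no view region — are
#' dropped and counted in the `bf_dropped` attribute. Trimming is
#' idempotent.
#'
#' @inheritParams bf_complement
#' @param region_col Name of the assignment column.
#' @return A tibble with the input's columns, coordinates clipped.
#' @examples
#' v <- bf_make_view(c(chr1 = 100))
#' bf_trim(tibble::tibble(chrom = "chr1", start = -5L, end = 50L), v)
#' @export
bf_trim <- function(df, view, cols = NULL, name_col = NULL,
                    region_col = "view_region") {
  cols <- resolve_cols(cols)
  name_col <- bf_name_col(name_col)
  assert_bedframe(df, cols)
  assert_viewframe(view, cols, name_col)
  df <- tibble::as_tibble(df)
  had_assignment <- region_col %in% names(df) &&
    all(is.na(df[[region_col]]) | df[[region_col]] %in% view[[name_col]])
  assigned <- if (had_assignment) {
    df[[region_col]]
  } else {
    bf_assign_view(df, view, cols = cols, name_col = name_col,
                   region_col = ".bf_region")$.bf_region
  }
  idx <- match(assigned, view[[name_col]])
  rs <- view[[cols[2L]]][idx]
  re <- view[[cols[3L]]][idx]
  s <- df[[cols[2L]]]
  e <- df[[cols[3L]]]
  ns <- pmax(s, rs)
  ne <- pmin(e, re)
  keep <- !is.na(idx) & !is.na(ns) & !is.na(ne) &
    (ns < ne | (s == e & ns == ne))
  out <- vctrs::vec_slice(df, keep)
  out[[cols[2L]]] <- as.integer(ns[keep])
  out[[cols[3L]]] <- as.integer(ne[keep])
  attr(out, "bf_dropped") <- sum(!keep)
  out
}

#' Select intervals overlapping a query region
#'
#' Filters a bedframe to the rows overlapping a query region given as a
#' UCSC-style string (`"chr1:10,000-20,000"`; see [parse_region()]) or a
#' `list(chrom, start, end)`. A bare chromosome name selects the whole
#' chromosome. The test is half-open, so bookended rows are excluded; set
#' `contained = TRUE` to keep only rows lying entirely within the query.
#'
#' @inheritParams bf_cluster
#' @param region Query region: string or `list(chrom, start, end)`.
#' @param contained Require full containment instead of any overlap.
#' @return The matching rows as a tibble.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(0L, 10L), end = c(10L, 20L))
#' bf_select(x, "chr1:5-10")
#' @export
bf_select <- function(df, region, contained = FALSE, cols = NULL) {
  cols <- resolve_cols(cols)
  assert_bedframe(df, cols)
  df <- tibble::as_tibble(df)
  q <- if (is.character(region)) {
    if (length(region) != 1L) {
      rlang::abort("`region` must be a single region string.",
                   class = "bf_error_validation")
    }
    as.list(parse_region(region))
  } else if (is.list(region) && length(region) == 3L) {
    stats::setNames(region, c("chrom", "start", "end"))
  } else {
    rlang::abort("`region` must be a string or list(chrom, start, end).",
                 class = "bf_error_validation")
  }
  on_chrom <- !is.na(df[[cols[1L]]]) & df[[cols[1L]]] == q$chrom
  if (is.null(q$start) || is.na(q$start)) {
    return(vctrs::vec_slice(df, on_chrom))
  }
  s <- df[[cols[2L]]]
  e <- df[[cols[3L]]]
  hit <- if (contained) {
    on_chrom & !is.na(s) & !is.na(e) & q$start <= s & e <= q$end
  } else {
    on_chrom & !is.na(s) & !is.na(e) & s < q$end & q$start < e
  }
  vctrs::vec_slice(df, hit)
}
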