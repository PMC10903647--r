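# Property checks on interval tables, individually and as a suite.

coords_of <- function(df, cols) {
  list(chrom = df[[cols[1L]]], start = df[[cols[2L]]], end = df[[cols[3L]]])
}

complete_coord_rows <- function(df, cols) {
  !is.na(df[[cols[1L]]]) & !is.na(df[[cols[2L]]]) & !is.na(df[[cols[3L]]])
}

abort_assignment_missing <- function(region_col) {
  rlang::abort(
    sprintf("assignment missing: table has no '%s' column; run bf_assign_view() first.",
            region_col),
    class = "bf_error_assignment")
}

#' Interval-table property checks
#'
#' Predicates over a bedframe, several of them relative to a genomic view:
#' \describe{
#'   \item{`bf_is_sorted()`}{rows are ordered by (chrom lexicographic, start,
#'     end), or by view region order when `view` is given.}
#'   \item{`bf_is_overlapping()`}{some pair of intervals on the same
#'     chromosome overlaps (half-open test).}
#'   \item{`bf_is_cataloged()`}{every value of the table's region-assignment
#'     column (`region_col`, default `"view_region"`) names a region present
#'     in `view`.}
#'   \item{`bf_is_contained()`}{every interval lies within the bounds of its
#'     assigned region (containment test: `region start <= start` and
#'     `end <= region end`).}
#'   \item{`bf_is_covering()`}{the union of intervals covers every base of
#'     every view region.}
#'   \item{`bf_is_tiling()`}{covering, non-overlapping and cataloged. When
#'     the table has no assignment column, intervals are assigned to regions
#'     internally via [bf_assign_view()].}
#' }
#' `bf_is_cataloged()` and `bf_is_contained()` raise a classed error
#' (`bf_error_assignment`) when the assignment column is absent.
#'
#' All checks are pure: they never modify their input.
#'
#' @param df A bedframe.
#' @param view A genomic view (see [is_viewframe()]).
#' @param cols,name_col Column configuration (see [bf_cols()]).
#' @param region_col Name of the table column holding region assignments.
#' @return A single logical.
#' @examples
#' v <- bf_make_view(c(chr1 = 100))
#' tiles <- tibble::tibble(chrom = "chr1", start = c(0L, 40L), end = c(40L, 100L))
#' bf_is_tiling(tiles, v)
#' @export
bf_is_sorted <- function(df, view = NULL, cols = NULL, name_col = NULL) {
  assert_bedframe(df, cols)
  sorted <- bf_sort(df, view = view, cols = cols, name_col = name_col)
  identical(unname(as.list(tibble::as_tibble(df))),
            unname(as.list(sorted)))
}

#' @rdname bf_is_sorted
#' @export
bf_is_overlapping <- function(df, cols = NULL) {
  cols <- resolve_cols(cols)
  assert_bedframe(df, cols)
  ok <- which(complete_coord_rows(df, cols))
  if (length(ok) < 2L) return(FALSE)
  cr <- coords_of(df, cols)
  for (chr in unique(cr$chrom[ok])) {
    ii <- ok[cr$chrom[ok] == chr]
    prs <- ivl_overlap_pairs(cr$start[ii], cr$end[ii], cr$start[ii], cr$end[ii])
    if (any(prs$id_a != prs$id_b)) return(TRUE)
  }
  FALSE
}

#' @rdname bf_is_sorted
#' @export
bf_is_cataloged <- function(df, view, cols = NULL, name_col = NULL,
                            region_col = "view_region") {
  assert_bedframe(df, cols)
  assert_viewframe(view, cols, name_col)
  if (!region_col %in% names(df)) abort_assignment_missing(region_col)
  nm <- df[[region_col]]
  all(is.na(nm) | nm %in% view[[bf_name_col(name_col)]]) && !anyNA(nm)
}

#' @rdname bf_is_sorted
#' @export
bf_is_contained <- function(df, view, cols = NULL, name_col = NULL,
                            region_col = "view_region") {
  cols <- resolve_cols(cols)
  name_col <- bf_name_col(name_col)
  assert_bedframe(df, cols)
  assert_viewframe(view, cols, name_col)
  if (!region_col %in% names(df)) abort_assignment_missing(region_col)
  idx <- match(df[[region_col]], view[[name_col]])
  if (anyNA(idx)) return(FALSE)
  rs <- view[[cols[2L]]][idx]
  re <- view[[cols[3L]]][idx]
  ok <- complete_coord_rows(df, cols)
  all(rs[ok] <= df[[cols[2L]]][ok] & df[[cols[3L]]][ok] <= re[ok]) &&
    all(df[[cols[1L]]][ok] == view[[cols[1L]]][idx][ok])
}

#' @rdname bf_is_sorted
#' @export
bf_is_covering <- function(df, view, cols = NULL, name_col = NULL) {
  assert_bedframe(df, cols)
  assert_viewframe(view, cols, name_col)
  gaps <- bf_complement(df, view, cols = cols, name_col = name_col)
  nrow(gaps) == 0L
}

#' @rdname bf_is_sorted
#' @export
bf_is_tiling <- function(df, view, cols = NULL, name_col = NULL,
                         region_col = "view_region") {
  cols <- resolve_cols(cols)
  assert_bedframe(df, cols)
  assert_viewframe(view, cols, name_col)
  tab <- tibble::as_tibble(df)
  if (!region_col %in% names(tab)) {
    tab <- bf_assign_view(tab, view, cols = cols, name_col = name_col,
                          region_col = region_col)
  }
  bf_is_covering(tab, view, cols = cols, name_col = name_col) &&
    !bf_is_overlapping(tab, cols = cols) &&
    bf_is_cataloged(tab, view, cols = cols, name_col = name_col,
                    region_col = region_col)
}

#' Run the whole checks suite
#'
#' Computes all six property checks where their inputs allow it. Checks that
#' require a view (`is_cataloged`, `is_contained`, `is_covering`,
#' `is_tiling`) are `NA` when `view` is `NULL`; `is_cataloged` and
#' `is_contained` are `NA` when the assignment column is absent.
#'
#' @inheritParams bf_is_sorted
#' @inheritParams bf_is_cataloged
#' @return A named logical vector with elements `is_sorted`,
#'   `is_overlapping`, `is_cataloged`, `is_contained`, `is_covering`,
#'   `is_tiling`.
#' @export
bf_checks <- function(df, view = NULL, cols = NULL, name_col = NULL,
                      region_col = "view_region") {
  out <- c(is_sorted = bf_is_sorted(df, view = view, cols = cols,
                                    name_col = name_col),
           is_overlapping = bf_is_overlapping(df, cols = cols),
           is_cataloged = NA, is_contained = NA, is_covering = NA,
           is_tiling = NA)
  if (!is.null(view)) {
    has_assign <- region_col %in% names(df)
    if (has_assign) {
      out["is_cataloged"] <- bf_is_cataloged(df, view, cols, name_col, region_col)
      out["is_contained"] <- bf_is_contained(df, view, cols, name_col, region_col)
    }
    out["is_covering"] <- bf_is_covering(df, view, cols, name_col)
    out["is_tiling"] <- bf_is_tiling(df, view, cols, name_col, region_col)
  }
  out
}
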