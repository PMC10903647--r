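# Interval-table data model: validation specifications and sanitising.
#
# A "bedframe" is any data frame carrying a chrom/start/end coordinate triple
# (names resolved through the scoped configuration) in 0-based half-open
# coordinates, plus any number of annotation columns. A "viewframe" (genomic
# view) additionally has a unique region-name column, non-missing coordinates
# and mutually non-overlapping regions; its row order defines the coordinate
# sub-system's region order.

abort_schema <- function(cols, df_name = "table") {
  rlang::abort(
    sprintf("%s does not contain the coordinate columns (%s): schema absent.",
            df_name, paste(cols, collapse = ", ")),
    class = "bf_error_schema")
}

is_whole_number <- function(x) {
  if (is.integer(x)) return(rep(TRUE, length(x)))
  is.finite(x) & x == trunc(x)
}

#' Validate a table against the bedframe specification
#'
#' `check_bedframe()` returns a full report; `is_bedframe()` just the verdict.
#' A valid bedframe has integer-valued `start <= end` wherever both are
#' present, non-missing `chrom` wherever coordinates are present, and may
#' carry any extra annotation columns (which impose no constraints). Rows
#' with *all three* coordinates missing are permitted; partial missingness is
#' a violation.
#'
#' @param df A data frame.
#' @param cols Coordinate column triple (see [bf_cols()]).
#' @return `check_bedframe()`: a list with `valid` (logical),
#'   `schema_present` (logical) and `violations`, a tibble with columns `row`
#'   and `violation`. Missing coordinate columns are reported as schema
#'   absence, not as row violations. `is_bedframe()`: a single logical.
#' @examples
#' is_bedframe(tibble::tibble(chrom = "chr1", start = 0L, end = 10L))
#' check_bedframe(tibble::tibble(chrom = "chr1", start = 10L, end = 0L))
#' @export
check_bedframe <- function(df, cols = NULL) {
  cols <- resolve_cols(cols)
  if (!is.data.frame(df) || !cols_present(df, cols)) {
    return(list(valid = FALSE, schema_present = FALSE,
                violations = tibble::tibble(row = integer(),
                                            violation = character())))
  }
  chrom <- df[[cols[1L]]]
  start <- df[[cols[2L]]]
  end <- df[[cols[3L]]]
  rows <- integer(0)
  what <- character(0)
  add <- function(idx, msg) {
    rows <<- c(rows, idx)
    what <<- c(what, rep(msg, length(idx)))
  }
  if (!is.numeric(start)) {
    add(0L, sprintf("column '%s' is not numeric", cols[2L]))
  } else {
    bad <- which(!is.na(start) & !is_whole_number(start))
    add(bad, "start not integer-valued")
  }
  if (!is.numeric(end)) {
    add(0L, sprintf("column '%s' is not numeric", cols[3L]))
  } else {
    bad <- which(!is.na(end) & !is_whole_number(end))
    add(bad, "end not integer-valued")
  }
  if (is.numeric(start) && is.numeric(end)) {
    bad <- which(!is.na(start) & !is.na(end) & start > end)
    add(bad, "start>end")
    part <- which(is.na(start) != is.na(end))
    add(part, "partially missing coordinates")
    coord_present <- !is.na(start) | !is.na(end)
    bad <- which(coord_present & is.na(chrom))
    add(bad, "chrom missing where coordinates present")
  }
  ord <- order(rows, method = "radix")
  viol <- tibble::tibble(row = rows[ord], violation = what[ord])
  list(valid = nrow(viol) == 0L, schema_present = TRUE, violations = viol)
}

#' @rdname check_bedframe
#' @export
is_bedframe <- function(df, cols = NULL) {
  check_bedframe(df, cols)$valid
}

#' Validate a table against the genomic-view specification
#'
#' A genomic view is an ordered set of uniquely-named, non-overlapping
#' regions: a valid bedframe with no missing coordinates, a non-missing and
#' duplicate-free name column, and no two regions overlapping under the
#' half-open test (bookended regions are fine). Multiple regions may share a
#' chromosome; row order is the region order.
#'
#' @inheritParams check_bedframe
#' @param name_col Region-name column (see [bf_name_col()]).
#' @return As [check_bedframe()] / [is_bedframe()].
#' @examples
#' v <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
#'                     end = c(100L, 200L), name = c("p", "q"))
#' is_viewframe(v)
#' @export
check_viewframe <- function(df, cols = NULL, name_col = NULL) {
  cols <- resolve_cols(cols)
  name_col <- bf_name_col(name_col)
  base <- check_bedframe(df, cols)
  if (!base$schema_present || !is.data.frame(df) ||
      !name_col %in% names(df)) {
    return(list(valid = FALSE, schema_present = FALSE,
                violations = base$violations))
  }
  rows <- base$violations$row
  what <- base$violations$violation
  start <- df[[cols[2L]]]
  end <- df[[cols[3L]]]
  nm <- df[[name_col]]
  miss <- which(is.na(start) | is.na(end))
  if (length(miss)) {
    rows <- c(rows, miss)
    what <- c(what, rep("missing coordinates", length(miss)))
  }
  badnm <- which(is.na(nm))
  if (length(badnm)) {
    rows <- c(rows, badnm)
    what <- c(what, rep("missing region name", length(badnm)))
  }
  dup <- which(duplicated(nm) & !is.na(nm))
  if (length(dup)) {
    rows <- c(rows, dup)
    what <- c(what, rep("duplicate region name", length(dup)))
  }
  # overlap test per chromosome, only on rows with complete coordinates
  ok <- !is.na(start) & !is.na(end) & !is.na(df[[cols[1L]]]) & start <= end
  idx <- which(ok)
  if (length(idx) > 1L) {
    for (chr in unique(df[[cols[1L]]][idx])) {
      ii <- idx[df[[cols[1L]]][idx] == chr]
      prs <- ivl_overlap_pairs(start[ii], end[ii], start[ii], end[ii])
      prs <- prs[prs$id_a < prs$id_b, ]
      if (nrow(prs)) {
        off <- unique(ii[prs$id_b])
        rows <- c(rows, off)
        what <- c(what, rep("overlapping regions", length(off)))
      }
    }
  }
  ord <- order(rows, method = "radix")
  viol <- tibble::tibble(row = rows[ord], violation = what[ord])
  list(valid = nrow(viol) == 0L, schema_present = TRUE, violations = viol)
}

#' @rdname check_viewframe
#' @export
is_viewframe <- function(df, cols = NULL, name_col = NULL) {
  check_viewframe(df, cols, name_col)$valid
}

assert_bedframe <- function(df, cols = NULL, df_name = "table") {
  cols <- resolve_cols(cols)
  chk <- check_bedframe(df, cols)
  if (!chk$schema_present) abort_schema(cols, df_name)
  if (!chk$valid) {
    first <- chk$violations[1L, ]
    rlang::abort(
      sprintf("%s is not a valid bedframe: %s (first at row %d; %d violation(s)).",
              df_name, first$violation, first$row, nrow(chk$violations)),
      class = "bf_error_validation")
  }
  invisible(TRUE)
}

assert_viewframe <- function(df, cols = NULL, name_col = NULL,
                             df_name = "view") {
  chk <- check_viewframe(df, cols, name_col)
  if (!chk$valid) {
    msg <- if (nrow(chk$violations)) {
      paste(utils::head(unique(chk$violations$violation), 3L), collapse = "; ")
    } else {
      "coordinate or name columns absent"
    }
    rlang::abort(sprintf("%s is not a valid genomic view: %s.", df_name, msg),
                 class = "bf_error_validation")
  }
  invisible(TRUE)
}

#' Coerce coordinate columns to NA-capable integers, optionally dropping bad rows
#'
#' Coordinates are coerced to R's integer type (which represents missing
#' values natively); numeric text such as `"5"` is parsed. With
#' `drop_invalid = TRUE`, rows violating `start <= end` or with partial
#' coordinate missingness are removed; the number removed is attached as the
#' `bf_dropped` attribute. On a table that already passes [is_bedframe()]
#' with complete coordinates, sanitising is the identity on coordinate
#' values.
#'
#' @inheritParams check_bedframe
#' @param drop_invalid Drop (rather than keep) rows violating the invariants.
#' @return A tibble; coordinate columns integer. Attribute `bf_dropped`
#'   counts removed rows (0 when `drop_invalid = FALSE`).
#' @examples
#' bf_sanitize(data.frame(chrom = "chr1", start = "5", end = "10"))
#' @export
bf_sanitize <- function(df, cols = NULL, drop_invalid = FALSE) {
  cols <- resolve_cols(cols)
  if (!is.data.frame(df) || !cols_present(df, cols)) abort_schema(cols)
  out <- tibble::as_tibble(df)
  for (cc in cols[2:3]) {
    x <- out[[cc]]
    if (is.character(x) || is.factor(x)) {
      x <- as.character(x)
      x[x %in% c(".", "")] <- NA_character_
      conv <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(conv))
      if (length(bad)) {
        rlang::abort(
          sprintf("column '%s': non-numeric coordinate '%s' at row %d.",
                  cc, x[bad[1L]], bad[1L]),
          class = "bf_error_validation")
      }
      x <- conv
    }
    if (!is.numeric(x) && !is.logical(x)) {
      rlang::abort(sprintf("column '%s' cannot be coerced to integer coordinates.", cc),
                   class = "bf_error_validation")
    }
    bad <- which(!is.na(x) & !is_whole_number(x))
    if (length(bad)) {
      rlang::abort(
        sprintf("column '%s': non-integer coordinate at row %d.", cc, bad[1L]),
        class = "bf_error_validation")
    }
    out[[cc]] <- if (all(is.na(x)) || max(abs(x), na.rm = TRUE) < .Machine$integer.max) {
      as.integer(x)
    } else {
      as.numeric(x)
    }
  }
  dropped <- 0L
  if (drop_invalid) {
    start <- out[[cols[2L]]]
    end <- out[[cols[3L]]]
    bad <- (!is.na(start) & !is.na(end) & start > end) |
      (is.na(start) != is.na(end)) |
      ((!is.na(start) | !is.na(end)) & is.na(out[[cols[1L]]]))
    dropped <- sum(bad)
    out <- out[!bad, , drop = FALSE]
  }
  attr(out, "bf_dropped") <- as.integer(dropped)
  out
}
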