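# Scoped configuration of coordinate column names.
#
# All bedframe operations resolve the (chrom, start, end) triple and the view
# name column through a stack of scopes held in a package-local environment.
# The innermost scope wins; exiting a scope always restores the previous
# configuration, even when the scope body throws.

.bf_config <- new.env(parent = emptyenv())
.bf_config$stack <- list(
  list(cols = c("chrom", "start", "end"), name_col = "name")
)

bf_current_config <- function() {
  .bf_config$stack[[length(.bf_config$stack)]]
}

check_cols_triple <- function(cols) {
  if (!is.character(cols) || length(cols) != 3L || anyNA(cols) ||
      any(!nzchar(cols))) {
    rlang::abort("`cols` must be three non-empty column names (chrom, start, end).",
                 class = "bf_error_config")
  }
  if (anyDuplicated(cols)) {
    rlang::abort("`cols` must be three *distinct* column names.",
                 class = "bf_error_config")
  }
  unname(cols)
}

#' Get or resolve the coordinate column names in force
#'
#' Returns the `(chrom, start, end)` triple that bedframe operations currently
#' resolve coordinate columns to. When `cols` is supplied it overrides the
#' active configuration for a single call; this is how every operation's
#' `cols` argument is interpreted.
#'
#' @param cols `NULL` (use the active configuration) or a character triple of
#'   column names.
#' @return A character vector of length three: chrom, start, end column names.
#' @seealso [with_bf_cols()] for scoped overrides, [set_bf_cols()] for a
#'   process-global default.
#' @examples
#' bf_cols()
#' bf_cols(c("CHR", "beg", "stop"))
#' @export
bf_cols <- function(cols = NULL) {
  if (is.null(cols)) {
    return(bf_current_config()$cols)
  }
  check_cols_triple(cols)
}

#' Get the view region-name column in force
#'
#' @param name_col `NULL` (use the active configuration) or a single column
#'   name.
#' @return A single column name used for view region names.
#' @export
bf_name_col <- function(name_col = NULL) {
  if (is.null(name_col)) {
    return(bf_current_config()$name_col)
  }
  if (!rlang::is_string(name_col) || !nzchar(name_col)) {
    rlang::abort("`name_col` must be a single non-empty column name.",
                 class = "bf_error_config")
  }
  name_col
}

#' Set the default coordinate column names globally
#'
#' Replaces the outermost (default) configuration. Scoped overrides created
#' with [with_bf_cols()] still win while they are active. The command-line
#' interface uses this for its `--cols` flag.
#'
#' @inheritParams bf_cols
#' @param name_col optional view region-name column to set alongside.
#' @return The previous configuration, invisibly (a list with `cols` and
#'   `name_col`), so it can be restored.
#' @export
set_bf_cols <- function(cols, name_col = NULL) {
  cols <- check_cols_triple(cols)
  old <- .bf_config$stack[[1L]]
  new <- old
  new$cols <- cols
  if (!is.null(name_col)) new$name_col <- bf_name_col(name_col)
  .bf_config$stack[[1L]] <- new
  invisible(old)
}

#' Evaluate code under a scoped coordinate-column configuration
#'
#' Inside the scope, every bedframe operation resolves coordinate columns to
#' `cols` (and view names to `name_col`). Scopes nest: the innermost wins, and
#' on exit — normal or via an error — the previous configuration is restored
#' exactly.
#'
#' @inheritParams set_bf_cols
#' @param code Code to evaluate within the scope.
#' @return The value of `code`.
#' @examples
#' df <- tibble::tibble(CHR = "chr1", beg = 0L, stop = 10L)
#' with_bf_cols(c("CHR", "beg", "stop"), is_bedframe(df))
#' @export
with_bf_cols <- function(cols, code, name_col = NULL) {
  local_bf_cols(cols, name_col = name_col)
  force(code)
}

#' @rdname with_bf_cols
#' @param .local_envir Environment whose exit pops the scope (advanced; the
#'   caller's frame by default, in the style of the withr package).
#' @export
local_bf_cols <- function(cols, name_col = NULL,
                          .local_envir = parent.frame()) {
  cols <- check_cols_triple(cols)
  cfg <- bf_current_config()
  cfg$cols <- cols
  if (!is.null(name_col)) cfg$name_col <- bf_name_col(name_col)
  .bf_config$stack[[length(.bf_config$stack) + 1L]] <- cfg
  withr::defer({
    .bf_config$stack[[length(.bf_config$stack)]] <- NULL
  }, envir = .local_envir)
  invisible(cfg)
}

# Resolve cols / name_col and verify presence in a table when required.
resolve_cols <- function(cols = NULL) bf_cols(cols)

cols_present <- function(df, cols) all(cols %in% names(df))
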