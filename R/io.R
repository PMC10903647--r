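# BED-family text I/O, chromsizes, and UCSC-style region strings.
#
# Readers tolerate any run of tabs/spaces as delimiters and skip leading
# "track"/"browser"/"#" header lines; writers emit strict single-tab BED
# with "." for missing values. Region strings are interpreted verbatim as
# 0-based half-open coordinates (the UCSC browser's 1-based inclusive
# reading can be requested explicitly).

#' BED-family column schemas
#'
#' The supported schemas and their ordered column names. The first three
#' columns of every schema are the coordinate triple; `bed6` adds `name`,
#' `score`, `strand`; `narrowPeak`/`broadPeak` are the ENCODE peak formats.
#'
#' @return A named list of character vectors of column names.
#' @export
bed_schemas <- function() {
  bed3 <- c("chrom", "start", "end")
  bed6 <- c(bed3, "name", "score", "strand")
  bed9 <- c(bed6, "thickStart", "thickEnd", "itemRgb")
  bed12 <- c(bed9, "blockCount", "blockSizes", "blockStarts")
  list(bed3 = bed3, bed6 = bed6, bed9 = bed9, bed12 = bed12,
       narrowPeak = c(bed6, "signalValue", "pValue", "qValue", "peak"),
       broadPeak = c(bed6, "signalValue", "pValue", "qValue"))
}

.bed_int_cols <- c("start", "end", "score", "thickStart", "thickEnd",
                   "blockCount", "peak")
.bed_dbl_cols <- c("signalValue", "pValue", "qValue")

#' Read a BED-family text file
#'
#' Delimiters are runs of tabs or spaces; leading `track`, `browser` and
#' `#` lines are skipped; `"."` is read as missing in non-coordinate
#' columns. In `"auto"` mode the schema is inferred from the column count
#' (3, 6, 9 or 12).
#'
#' @param path File path (or connection).
#' @param schema One of `"auto"`, `"bed3"`, `"bed6"`, `"bed9"`, `"bed12"`,
#'   `"narrowPeak"`, `"broadPeak"`.
#' @return A tibble with columns named per the schema; coordinates integer.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t10\tA\t960\t+", p)
#' read_bed(p)
#' @export
read_bed <- function(path, schema = "auto") {
  schemas <- bed_schemas()
  if (!identical(schema, "auto") && !schema %in% names(schemas)) {
    rlang::abort(sprintf("unknown BED schema '%s'.", schema),
                 class = "bf_error_io")
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track\\b|browser\\b|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    sc <- if (identical(schema, "auto")) "bed3" else schema
    return(empty_bed(schemas[[sc]]))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    rlang::abort(sprintf("inconsistent column count at line %d.", line_no[bad]),
                 class = "bf_error_io")
  }
  ncol <- nf[1L]
  if (identical(schema, "auto")) {
    schema <- switch(as.character(ncol), "3" = "bed3", "6" = "bed6",
                     "9" = "bed9", "12" = "bed12", NULL)
    if (is.null(schema)) {
      rlang::abort(sprintf(
        "cannot infer a BED schema from %d columns (expected 3, 6, 9 or 12).",
        ncol), class = "bf_error_io")
    }
  }
  want <- schemas[[schema]]
  if (ncol != length(want)) {
    rlang::abort(sprintf("schema '%s' expects %d columns, file has %d.",
                         schema, length(want), ncol),
                 class = "bf_error_io")
  }
  mat <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  out <- tibble::as_tibble(stats::setNames(as.data.frame(mat,
                                                         stringsAsFactors = FALSE),
                                           want))
  for (j in seq_along(want)) {
    cn <- want[j]
    x <- out[[cn]]
    if (cn %in% c("start", "end")) {
      v <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(v) | v != trunc(v))
      if (length(bad)) {
        rlang::abort(sprintf("non-integer coordinate '%s' in column '%s' at line %d.",
                             x[bad[1L]], cn, line_no[bad[1L]]),
                     class = "bf_error_io")
      }
      out[[cn]] <- as.integer(v)
    } else if (cn %in% .bed_int_cols) {
      x[x == "."] <- NA
      out[[cn]] <- suppressWarnings(as.integer(x))
    } else if (cn %in% .bed_dbl_cols) {
      x[x == "."] <- NA
      out[[cn]] <- suppressWarnings(as.numeric(x))
    }
  }
  names(out)[1:3] <- resolve_cols(NULL)  # triple follows the active config
  out
}

empty_bed <- function(want) {
  out <- lapply(want, function(cn) {
    if (cn %in% c("start", "end") || cn %in% .bed_int_cols) integer()
    else if (cn %in% .bed_dbl_cols) numeric()
    else character()
  })
  out <- tibble::as_tibble(stats::setNames(out, want))
  names(out)[1:3] <- resolve_cols(NULL)
  out
}

#' Write a bedframe as BED text
#'
#' Tab-separated, no header, rows in table order, missing values as `"."`.
#' With a `schema`, exactly the schema's columns are written in schema
#' order: the coordinate triple (resolved through `cols`) is required, and
#' any other schema column absent from the table is filled with `"."`.
#' With `schema = NULL`, the table's columns are written as-is.
#'
#' @inheritParams bf_cluster
#' @param path Output file path.
#' @param schema A schema name from [bed_schemas()], or `NULL`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, schema = NULL, cols = NULL) {
  cols <- resolve_cols(cols)
  if (!is.data.frame(df) || !cols_present(df, cols)) abort_schema(cols)
  df <- tibble::as_tibble(df)
  if (!is.null(schema)) {
    schemas <- bed_schemas()
    if (!schema %in% names(schemas)) {
      rlang::abort(sprintf("unknown BED schema '%s'.", schema),
                   class = "bf_error_io")
    }
    want <- schemas[[schema]]
    out <- tibble::tibble(.rows = nrow(df))
    std <- stats::setNames(cols, c("chrom", "start", "end"))
    for (cn in want) {
      src <- if (cn %in% names(std)) std[[cn]] else cn
      if (cn %in% c("chrom", "start", "end") && !src %in% names(df)) {
        rlang::abort(sprintf("required coordinate column '%s' is missing.", src),
                     class = "bf_error_io")
      }
      out[[cn]] <- if (src %in% names(df)) df[[src]] else NA
    }
    df <- out
  }
  fmt <- lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "."
    x
  })
  lines <- do.call(paste, c(fmt, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Parse UCSC-style region strings
#'
#' Grammar: `CHROM` or `CHROM:START-END`; commas are allowed in numbers
#' (`"chr1:10,000-20,000"`). Numbers are taken verbatim as 0-based half-open
#' coordinates by default; `one_based = TRUE` interprets them as the UCSC
#' browser's 1-based inclusive convention and converts. A bare chromosome
#' name yields missing bounds (the whole chromosome); `start <= end` is
#' enforced and zero-length queries (`"chr1:5-5"`) are valid.
#'
#' @param x Character vector of region strings.
#' @param one_based Treat numbers as 1-based inclusive and convert.
#' @return A tibble with columns `chrom` (character) and `start`, `end`
#'   (integer; `NA` for bare chromosome names).
#' @examples
#' parse_region(c("chr1:1,000-2,000", "chrX"))
#' @export
parse_region <- function(x, one_based = FALSE) {
  if (!is.character(x) || !length(x)) {
    rlang::abort("`x` must be a non-empty character vector.",
                 class = "bf_error_io")
  }
  m <- regmatches(x, regexec("^(.*[^:]):([0-9,]+)-([0-9,]+)$", x))
  chrom <- character(length(x))
  start <- rep(NA_integer_, length(x))
  end <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    mi <- m[[i]]
    if (length(mi) == 4L) {
      chrom[i] <- mi[2L]
      start[i] <- as.integer(gsub(",", "", mi[3L], fixed = TRUE))
      end[i] <- as.integer(gsub(",", "", mi[4L], fixed = TRUE))
    } else {
      chrom[i] <- x[i]
    }
    if (is.na(chrom[i]) || !nzchar(chrom[i]) || grepl("[ \t]", chrom[i]) ||
        startsWith(chrom[i], ":")) {
      rlang::abort(sprintf("malformed region string '%s'.", x[i]),
                   class = "bf_error_io")
    }
  }
  if (one_based) {
    start <- start - 1L
  }
  bad <- which(!is.na(start) & start > end)
  if (length(bad)) {
    rlang::abort(sprintf("region '%s' has start > end.", x[bad[1L]]),
                 class = "bf_error_io")
  }
  tibble::tibble(chrom = chrom, start = start, end = end)
}

#' Format regions as UCSC-style strings
#'
#' The inverse of [parse_region()] (without digit grouping):
#' `"chrom:start-end"`, or just `chrom` when bounds are missing.
#'
#' @param chrom Character vector, or a bedframe (then `start`/`end` are
#'   taken from its coordinate columns).
#' @param start,end Integer vectors.
#' @param cols Coordinate columns used when `chrom` is a data frame.
#' @return A character vector.
#' @export
format_region <- function(chrom, start = NULL, end = NULL, cols = NULL) {
  if (is.data.frame(chrom)) {
    cols <- resolve_cols(cols)
    df <- chrom
    chrom <- df[[cols[1L]]]
    start <- df[[cols[2L]]]
    end <- df[[cols[3L]]]
  }
  ifelse(is.na(start) | is.na(end),
         as.character(chrom),
         paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE),
                "-", format(end, scientific = FALSE, trim = TRUE)))
}

#' Read a chromsizes file
#'
#' Two whitespace-separated columns: scaffold name and length. File order is
#' preserved (it becomes the region order of a view built from the result).
#'
#' @param path File path.
#' @return A named numeric vector of positive lengths, in file order.
#' @examples
#' p <- tempfile()
#' writeLines(c("chr1\t100", "chr2\t50"), p)
#' read_chromsizes(p)
#' @export
read_chromsizes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) != 2L)) {
    rlang::abort("chromsizes lines must have exactly two fields.",
                 class = "bf_error_io")
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(len) || any(len <= 0 | len != trunc(len))) {
    rlang::abort("chromsizes lengths must be positive integers.",
                 class = "bf_error_io")
  }
  if (anyDuplicated(nm)) {
    rlang::abort(sprintf("duplicate chromosome '%s' in chromsizes.",
                         nm[duplicated(nm)][1L]),
                 class = "bf_error_io")
  }
  stats::setNames(len, nm)
}
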