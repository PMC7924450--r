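#' Read a time series from a text file
#'
#' Accepts either a single-column headerless file of numbers or a delimited
#' file (CSV/TSV) with a header row, from which one named column is
#' extracted. Non-numeric entries and missing values are rejected with a
#' line-numbered error rather than imputed: silently filling gaps would
#' change the causality estimate, whereas genuinely removed samples are
#' handled by the estimator itself.
#'
#' @param path path to the file.
#' @param column column name to extract from a file with a header; `NULL`
#'   (default) for a single-column headerless file (a lone header-less
#'   column in a one-column CSV is also accepted).
#' @return a numeric vector.
#' @export
read_series <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  if (is.null(column)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty file: ", path)
    vals <- suppressWarnings(as.numeric(lines))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop("non-numeric entry at line ", bad, " of ", path, ": '",
           lines[bad], "'")
    }
    return(vals)
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!column %in% names(df))
    stop("column '", column, "' not found in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  v <- df[[column]]
  vals <- suppressWarnings(as.numeric(v))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("non-numeric or missing entry in column '", column, "' at data line ",
         bad, " of ", path)
  }
  vals
}

#' Write a time series to a text file
#'
#' Writes one value per line with 12 significant digits, so
#' `read_series(write_series(x, path))` round-trips values to text
#' precision.
#'
#' @param x numeric series.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  writeLines(formatC(x, digits = 12, format = "g"), path)
  invisible(path)
}
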