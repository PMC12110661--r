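# Series file I/O: plain text, one decimal value per line; a single-column
# CSV with a header row is also accepted.

#' Read a time series from a text file
#'
#' Accepts one value per line, or a single-column CSV whose first line is a
#' non-numeric header (which is skipped). Anything else is an error.
#'
#' @param path input file.
#' @return numeric vector.
#' @export
read_series <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop(sprintf("empty series file: %s", path), call. = FALSE)
  first <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(first)) lines <- lines[-1L]  # header row
  vals <- suppressWarnings(as.numeric(lines))
  if (length(vals) == 0L || anyNA(vals))
    stop(sprintf("unparseable series file: %s", path), call. = FALSE)
  vals
}

#' Write a time series to a text file
#'
#' One value per line, formatted with 17 significant digits so that the
#' file round-trips through [read_series()] bit-exactly and identical
#' inputs produce identical file bytes.
#'
#' @param x numeric vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  writeLines(sprintf("%.17g", x), path)
  invisible(path)
}
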