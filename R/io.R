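# Plain-text square-matrix readers and writers (whitespace- or
# comma-delimited, optional single header row of column labels).

#' Read a square symmetric matrix from a delimited text file
#'
#' Parses a plain-text numeric grid. The delimiter is auto-detected (comma
#' if any comma appears on the first data line, otherwise whitespace) unless
#' given explicitly. A single optional header row of column labels is
#' accepted and attached as `dimnames`. The parsed grid is validated with
#' [validate_matrix()].
#'
#' @param path Path to the file.
#' @param delimiter `"auto"`, `"comma"` or `"whitespace"`.
#' @param symmetry.tol Passed to [validate_matrix()].
#' @return A validated symmetric numeric matrix.
#' @details Parse failures carry line numbers: ragged rows raise
#'   `pdbend_parse_error`, as do non-numeric cells outside a first header
#'   row.
#' @export
read_matrix <- function(path, delimiter = c("auto", "comma", "whitespace"),
                        symmetry.tol = 1e-8) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) {
    pdbend_error(sprintf("file not found: %s", path), "pdbend_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0) {
    pdbend_error(sprintf("no data in file: %s", path), "pdbend_parse_error")
  }
  split_line <- function(x) {
    if (delimiter == "comma") strsplit(trimws(x), "\\s*,\\s*")[[1]]
    else strsplit(trimws(x), "\\s+")[[1]]
  }
  if (delimiter == "auto") {
    delimiter <- if (grepl(",", lines[keep[1]])) "comma" else "whitespace"
  }
  tokens <- lapply(lines[keep], split_line)

  labels <- NULL
  first <- suppressWarnings(as.numeric(tokens[[1]]))
  if (any(is.na(first))) {
    labels <- tokens[[1]]
    tokens <- tokens[-1]
    keep <- keep[-1]
    if (length(tokens) == 0) {
      pdbend_error("file contains a header row but no data rows",
                   "pdbend_parse_error")
    }
  }

  ncols <- length(tokens[[1]])
  rows <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    if (length(tokens[[i]]) != ncols) {
      pdbend_error(
        sprintf("line %d: expected %d fields, found %d",
                keep[i], ncols, length(tokens[[i]])),
        "pdbend_parse_error"
      )
    }
    vals <- suppressWarnings(as.numeric(tokens[[i]]))
    if (any(is.na(vals) & !(tokens[[i]] %in% c("NA", "NaN")))) {
      bad <- tokens[[i]][which(is.na(vals))[1]]
      pdbend_error(
        sprintf("line %d: non-numeric value '%s'", keep[i], bad),
        "pdbend_parse_error"
      )
    }
    rows[[i]] <- vals
  }
  M <- do.call(rbind, rows)
  validate_matrix(M, symmetry.tol, labels = labels)
}

#' Write a matrix to a delimited text file
#'
#' Writes a numeric matrix with fixed decimal precision, so that
#' `read_matrix(write_matrix(M, path, p))` reproduces `M` within `10^-p`.
#' Column labels (`dimnames`) are written as a header row when present.
#'
#' @param M Numeric matrix.
#' @param path Output path.
#' @param precision Number of decimal digits (default 10).
#' @param delimiter `"whitespace"` or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path, precision = 10,
                         delimiter = c("whitespace", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!is.character(path) || length(path) != 1 || !nzchar(path)) {
    pdbend_error("invalid output path", "pdbend_io_error")
  }
  sep <- if (delimiter == "comma") "," else " "
  lines <- apply(M, 1, function(r) {
    paste(formatC(r, digits = precision, format = "f"), collapse = sep)
  })
  if (!is.null(colnames(M))) {
    lines <- c(paste(colnames(M), collapse = sep), lines)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    pdbend_error(sprintf("could not write to: %s", path), "pdbend_io_error")
  }
  invisible(path)
}
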