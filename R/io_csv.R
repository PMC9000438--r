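#' Read a spectral dataset from a CSV matrix
#'
#' Two on-disk layouts are supported. With `orientation = "columns"` the
#' first column holds the wavenumber axis and every further column is one
#' spectrum whose header cell is its id. With `orientation = "rows"` the
#' header row holds the wavenumbers (after a leading id cell) and every
#' further row is one spectrum. The dialect is fixed: comma separator,
#' '.' decimal, UTF-8, mandatory header row.
#'
#' @param path CSV file path.
#' @param orientation `"columns"` (default) or `"rows"`, see above.
#' @return An [ir_dataset()] with ascending axis; a descending on-disk axis
#'   is reversed consistently.
#' @seealso [write_spectra_csv()]
#' @export
read_spectra_csv <- function(path, orientation = c("columns", "rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    ir_stop(sprintf("cannot read '%s'", path), "ir_io_error")
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    ir_stop(sprintf("'%s' has no spectra", path), "ir_shape_error")

  to_num <- function(x, what) {
    y <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(y) & !(trimws(x) %in% c("NA", "")))
    if (length(bad))
      ir_stop(sprintf("non-numeric cell '%s' in %s of '%s'",
                      x[bad[1L]], what, path), "ir_parse_error")
    if (anyNA(y))
      ir_stop(sprintf("missing value in %s of '%s'", what, path),
              "ir_parse_error")
    y
  }

  if (orientation == "columns") {
    axis <- to_num(raw[[1L]], "wavenumber column")
    ids <- colnames(raw)[-1L]
    m <- vapply(seq_along(ids) + 1L,
                function(j) to_num(raw[[j]], sprintf("column '%s'", colnames(raw)[j])),
                numeric(nrow(raw)))
    m <- t(m)                       # spectra as rows internally
  } else {
    axis <- to_num(colnames(raw)[-1L], "wavenumber header row")
    ids <- raw[[1L]]
    m <- t(vapply(seq_len(nrow(raw)), function(i) {
      to_num(unlist(raw[i, -1L], use.names = FALSE),
             sprintf("row '%s'", ids[i]))
    }, numeric(length(axis))))
  }
  ir_dataset(axis, m, ids = ids)
}

#' Write a spectral dataset to a CSV matrix
#'
#' Inverse of [read_spectra_csv()]; values are written with 15 significant
#' digits so a read/write round trip preserves them to formatting precision.
#'
#' @param dataset An `ir_dataset`.
#' @param path Output CSV path.
#' @param orientation Layout, as in [read_spectra_csv()].
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(dataset, path, orientation = c("columns", "rows")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(dataset, "ir_dataset"))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) ir_stop(
                    sprintf("cannot write '%s': %s", path, conditionMessage(e)),
                    "ir_io_error"))
  on.exit(close(con))
  if (orientation == "columns") {
    writeLines(paste(c("wavenumber", dataset$ids), collapse = ","), con)
    fm <- matrix(fmt(dataset$matrix), nrow = nrow(dataset$matrix))
    writeLines(vapply(seq_along(dataset$axis), function(k)
      paste(c(fmt(dataset$axis[k]), fm[, k]), collapse = ","),
      character(1L)), con)
  } else {
    writeLines(paste(c("id", fmt(dataset$axis)), collapse = ","), con)
    writeLines(vapply(seq_along(dataset$ids), function(i)
      paste(c(dataset$ids[i], fmt(dataset$matrix[i, ])), collapse = ","),
      character(1L)), con)
  }
  invisible(path)
}
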