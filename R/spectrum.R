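#' Construct a single infrared spectrum
#'
#' A spectrum is one absorbance trace on a wavenumber axis. On construction
#' the axis is canonicalized to strictly ascending order (computation never
#' depends on the conventional reversed display order of IR spectra).
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1; finite and
#'   strictly positive, no duplicates. Any input order is accepted and
#'   sorted ascending, with `absorbance` permuted consistently.
#' @param absorbance Numeric vector of unitless absorbance values, same
#'   length as `wavenumbers`; all values must be finite.
#' @param id Character label for the spectrum.
#' @return An object of class `ir_spectrum`: a list with fields
#'   `wavenumbers`, `absorbance`, `id`.
#' @examples
#' s <- ir_spectrum(c(1000, 1001, 1002), c(0.1, 0.2, 0.15), id = "example")
#' s$wavenumbers
#' @export
ir_spectrum <- function(wavenumbers, absorbance, id = "spectrum") {
  if (!is.numeric(wavenumbers) || !is.numeric(absorbance))
    ir_stop("wavenumbers and absorbance must be numeric", "ir_contract_error")
  if (length(wavenumbers) != length(absorbance))
    ir_stop(sprintf("axis length %d != absorbance length %d",
                    length(wavenumbers), length(absorbance)),
            "ir_shape_error")
  if (length(wavenumbers) < 1L)
    ir_stop("a spectrum needs at least one channel", "ir_contract_error")
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)) || any(wavenumbers <= 0))
    ir_stop("wavenumbers must be finite and > 0", "ir_axis_error")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    ir_stop(sprintf("non-finite absorbance in spectrum '%s'", id),
            "ir_parse_error")
  if (anyDuplicated(wavenumbers))
    ir_stop(sprintf("duplicated wavenumber %.6g in spectrum '%s'",
                    wavenumbers[duplicated(wavenumbers)][1L], id),
            "ir_axis_error")
  ord <- order(wavenumbers)
  structure(list(wavenumbers = as.numeric(wavenumbers[ord]),
                 absorbance  = as.numeric(absorbance[ord]),
                 id          = as.character(id)[1L]),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum '%s': %d channels, %.4g-%.4g cm-1>\n",
              x$id, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Construct a spectral dataset
#'
#' A collection of spectra sharing one wavenumber axis, stored as an
#' n_spectra x n_channels absorbance matrix.
#'
#' @param axis Numeric shared wavenumber axis (cm^-1); validated and
#'   canonicalized like [ir_spectrum()].
#' @param matrix Numeric matrix, one row per spectrum, `length(axis)`
#'   columns; all values finite.
#' @param ids Character vector of unique spectrum labels, one per row.
#' @return An object of class `ir_dataset` with fields `axis`, `matrix`
#'   (rownames set to `ids`) and `ids`.
#' @export
ir_dataset <- function(axis, matrix, ids = NULL) {
  matrix <- as.matrix(matrix)
  if (is.null(ids)) ids <- rownames(matrix)
  if (is.null(ids)) ids <- sprintf("spectrum_%03d", seq_len(nrow(matrix)))
  if (!is.numeric(axis) || anyNA(axis) || any(!is.finite(axis)) || any(axis <= 0))
    ir_stop("axis wavenumbers must be finite and > 0", "ir_axis_error")
  if (anyDuplicated(axis))
    ir_stop(sprintf("duplicated wavenumber %.6g in axis",
                    axis[duplicated(axis)][1L]), "ir_axis_error")
  if (ncol(matrix) != length(axis))
    ir_stop(sprintf("matrix has %d columns but axis has %d channels",
                    ncol(matrix), length(axis)), "ir_shape_error")
  if (length(ids) != nrow(matrix))
    ir_stop("one id per spectrum required", "ir_shape_error")
  if (anyDuplicated(ids))
    ir_stop(sprintf("duplicated spectrum id '%s'", ids[duplicated(ids)][1L]),
            "ir_contract_error")
  if (!is.numeric(matrix) || anyNA(matrix) || any(!is.finite(matrix))) {
    bad <- which(!is.finite(matrix), arr.ind = TRUE)
    ir_stop(sprintf("non-finite absorbance in spectrum '%s'",
                    ids[bad[1L, "row"]]), "ir_parse_error")
  }
  ord <- order(axis)
  m <- matrix[, ord, drop = FALSE]
  dimnames(m) <- list(as.character(ids), NULL)
  structure(list(axis = as.numeric(axis[ord]), matrix = m,
                 ids = as.character(ids)),
            class = "ir_dataset")
}

#' @export
print.ir_dataset <- function(x, ...) {
  cat(sprintf("<ir_dataset: %d spectra x %d channels, %.4g-%.4g cm-1>\n",
              nrow(x$matrix), ncol(x$matrix), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Extract one spectrum from a dataset
#'
#' @param dataset An `ir_dataset`.
#' @param which Row index or spectrum id.
#' @return An `ir_spectrum` on the dataset axis.
#' @export
get_spectrum <- function(dataset, which) {
  stopifnot(inherits(dataset, "ir_dataset"))
  if (is.character(which)) {
    i <- match(which, dataset$ids)
    if (is.na(i))
      ir_stop(sprintf("no spectrum with id '%s'", which), "ir_contract_error")
  } else i <- as.integer(which)
  ir_spectrum(dataset$axis, dataset$matrix[i, ], id = dataset$ids[i])
}

#' Resample a spectrum onto a target wavenumber axis
#'
#' Linear interpolation at each target wavenumber; where a target equals a
#' source channel the source value passes through exactly. Extrapolation is
#' refused: every target must lie inside the source axis range.
#'
#' @param spectrum An `ir_spectrum`.
#' @param target_axis Numeric vector of target wavenumbers (cm^-1), all
#'   within `range(spectrum$wavenumbers)`.
#' @return An `ir_spectrum` on `target_axis` (ascending).
#' @export
resample_spectrum <- function(spectrum, target_axis) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  wn <- spectrum$wavenumbers
  if (length(wn) < 2L)
    ir_stop("resampling needs at least two source channels", "ir_contract_error")
  out <- target_axis < min(wn) | target_axis > max(wn)
  if (any(out))
    ir_stop(sprintf("target wavenumber %.6g cm-1 outside source range [%.6g, %.6g]",
                    target_axis[out][1L], min(wn), max(wn)),
            "ir_range_error")
  y <- stats::approx(wn, spectrum$absorbance, xout = target_axis,
                     method = "linear", ties = "ordered")$y
  ir_spectrum(target_axis, y, id = spectrum$id)
}

# indices of axis channels inside a region specification: NULL (all), a
# c(lo, hi) pair, or a list of such pairs (union); endpoints inclusive.
region_indices <- function(axis, region) {
  if (is.null(region)) return(seq_along(axis))
  if (is.numeric(region) && length(region) == 2L) region <- list(region)
  if (!is.list(region) || !all(vapply(region, length, 1L) == 2L))
    ir_stop("region must be c(lo, hi) or a list of such pairs",
            "ir_contract_error")
  keep <- rep(FALSE, length(axis))
  for (rg in region) {
    rg <- sort(as.numeric(rg))
    keep <- keep | (axis >= rg[1L] & axis <= rg[2L])
  }
  which(keep)
}

same_axis <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && max(abs(a - b)) <= tol * max(1, max(abs(a)))
}
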