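#' @section Model:
#' Each measured spectrum Z(nu) is modelled around a reference spectrum
#' Z_ref(nu) as
#'   Z(nu) = a + b * Z_ref(nu) + eps(nu),
#' with additive baseline a, multiplicative scaling b and residual eps.
#' (a, b) are the ordinary least-squares solution over the fit region; the
#' residual RMSE, sqrt(mean(eps^2)), gauges dissimilarity to the reference.
#' @name msc-model
#' @keywords internal
NULL

# shared least-squares core: Z is an m x n matrix (spectra as rows), r the
# reference over the same channels. Mean-centering the reference before the
# solve conditions the normal equations; parameters are mapped back to the
# (a, b) parameterization of the model. Returns a, b, rmse and residuals.
msc_ls <- function(Z, r, want_residuals = TRUE) {
  n <- length(r)
  rc <- r - mean(r)
  ss <- sum(rc^2)
  if (ss <= (1e-14 * max(1, max(abs(r))))^2 * n)
    ir_stop("reference is constant over the fit region (rank-deficient design)",
            "ir_numeric_error")
  b <- as.numeric(Z %*% rc) / ss
  a <- rowMeans(Z) - b * mean(r)
  res <- Z - outer(a, rep(1, n)) - outer(b, r)
  rmse <- sqrt(rowMeans(res^2))
  list(a = a, b = b, rmse = rmse,
       residuals = if (want_residuals) res else NULL)
}

#' Fit the multiplicative signal correction model to one spectrum
#'
#' Ordinary least squares of the spectrum on (constant, reference) over the
#' fit region: `Z = a + b * Z_ref + eps`. The residual and its RMSE are
#' computed over the region only.
#'
#' @param spectrum An `ir_spectrum`.
#' @param reference An `ir_spectrum` on the same axis (resample first with
#'   [resample_spectrum()] if axes differ).
#' @param region Fit region: `NULL` for the full axis, `c(lo, hi)` in cm^-1,
#'   or a list of such intervals (union, endpoints inclusive). Must select
#'   at least 3 channels.
#' @return An object of class `ir_msc_fit`: list with `a`, `b`, `residual`,
#'   `rmse`, `region`, `indices` (axis positions used) and `id`.
#' @examples
#' axis <- seq(500, 2000, by = 2)
#' ref <- ir_spectrum(axis, exp(-(axis - 1630)^2 / 7200), id = "water")
#' z <- ir_spectrum(axis, 0.5 + 2 * ref$absorbance, id = "scaled")
#' fit <- fit_msc(z, ref)
#' c(fit$a, fit$b, fit$rmse)   # 0.5, 2, 0
#' @export
fit_msc <- function(spectrum, reference, region = NULL) {
  stopifnot(inherits(spectrum, "ir_spectrum"),
            inherits(reference, "ir_spectrum"))
  if (!same_axis(spectrum$wavenumbers, reference$wavenumbers))
    ir_stop(sprintf("spectrum '%s' and reference '%s' are on different axes; resample first",
                    spectrum$id, reference$id), "ir_contract_error")
  idx <- region_indices(spectrum$wavenumbers, region)
  if (length(idx) < 3L)
    ir_stop(sprintf("fit region selects %d channels; at least 3 required",
                    length(idx)), "ir_region_error")
  f <- msc_ls(matrix(spectrum$absorbance[idx], nrow = 1L),
              reference$absorbance[idx])
  structure(list(a = f$a[1L], b = f$b[1L],
                 residual = as.numeric(f$residuals[1L, ]),
                 rmse = f$rmse[1L],
                 region = if (is.null(region)) range(spectrum$wavenumbers) else region,
                 indices = idx, id = spectrum$id),
            class = "ir_msc_fit")
}

#' @export
print.ir_msc_fit <- function(x, ...) {
  cat(sprintf("<ir_msc_fit '%s': a = %.6g, b = %.6g, rmse = %.6g over %d channels>\n",
              x$id, x$a, x$b, x$rmse, length(x$indices)))
  invisible(x)
}

#' Root mean squared error of a residual vector
#'
#' `sqrt(sum(eps_i^2) / n)` over the n residual channels.
#'
#' @param residual Non-empty numeric residual vector (absorbance units).
#' @return The RMSE (absorbance units).
#' @export
rmse_of <- function(residual) {
  if (length(residual) == 0L)
    ir_stop("empty residual", "ir_contract_error")
  if (anyNA(residual) || any(!is.finite(residual)))
    ir_stop("non-finite residual", "ir_numeric_error")
  sqrt(sum(residual^2) / length(residual))
}

#' Threshold rule: water or cartilage
#'
#' A spectrum is labelled `water` when its MSC residual RMSE is less than
#' or equal to the threshold theta (boundary inclusive on the water side),
#' and `cartilage` otherwise.
#'
#' @param rmse Numeric RMSE value(s), finite and >= 0.
#' @param threshold Positive RMSE threshold theta (absorbance units).
#' @return Character vector of labels, `"water"` or `"cartilage"`.
#' @export
classify_rmse <- function(rmse, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0)
    ir_stop("threshold theta must be a single positive number",
            "ir_contract_error")
  if (anyNA(rmse) || any(!is.finite(rmse)) || any(rmse < 0))
    ir_stop("rmse must be finite and non-negative", "ir_contract_error")
  ifelse(rmse <= threshold, "water", "cartilage")
}

#' Preclassify every spectrum of a dataset against a reference
#'
#' Fits the MSC model to each row of the dataset against the reference
#' (water by convention; any reference spectrum may be supplied) and labels
#' each spectrum by the threshold rule of [classify_rmse()]. Deterministic;
#' row order is preserved.
#'
#' @param dataset An `ir_dataset`.
#' @param reference An `ir_spectrum` on the dataset axis.
#' @param threshold Positive RMSE threshold theta.
#' @param region Fit region, as in [fit_msc()].
#' @return A data.frame of class `ir_preclass` with columns `id`, `a`, `b`,
#'   `rmse`, `threshold`, `label` (one row per spectrum, input order).
#' @export
preclassify <- function(dataset, reference, threshold, region = NULL) {
  stopifnot(inherits(dataset, "ir_dataset"),
            inherits(reference, "ir_spectrum"))
  if (!same_axis(dataset$axis, reference$wavenumbers))
    ir_stop("reference is not on the dataset axis; resample first",
            "ir_contract_error")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0)
    ir_stop("threshold theta must be a single positive number",
            "ir_contract_error")
  idx <- region_indices(dataset$axis, region)
  if (length(idx) < 3L)
    ir_stop(sprintf("fit region selects %d channels; at least 3 required",
                    length(idx)), "ir_region_error")
  f <- msc_ls(dataset$matrix[, idx, drop = FALSE],
              reference$absorbance[idx], want_residuals = FALSE)
  out <- data.frame(id = dataset$ids, a = f$a, b = f$b, rmse = f$rmse,
                    threshold = threshold,
                    label = classify_rmse(f$rmse, threshold),
                    stringsAsFactors = FALSE)
  class(out) <- c("ir_preclass", "data.frame")
  out
}

#' Midpoint of the gap between two separated value clusters
#'
#' For two groups of values whose distributions are disjoint (e.g. the MSC
#' RMSEs of water-like and analyte-rich spectra, or two clusters of SNR
#' ratios), returns the midpoint of the empty interval between them:
#' `(max(lower) + min(upper)) / 2`. Any threshold in the gap separates the
#' groups perfectly; the midpoint is the canonical deterministic choice.
#' Warns when the groups overlap (the returned value then separates
#' nothing cleanly).
#'
#' @param lower,upper Numeric value vectors for the low and high cluster.
#' @return A single numeric threshold.
#' @export
gap_midpoint <- function(lower, upper) {
  if (!length(lower) || !length(upper))
    ir_stop("both clusters must be non-empty", "ir_contract_error")
  lo <- max(lower); hi <- min(upper)
  if (lo >= hi)
    warning(sprintf("clusters overlap (max lower %.6g >= min upper %.6g)",
                    lo, hi))
  (lo + hi) / 2
}

#' Write preclassification results as TSV
#'
#' Columns `id`, `a`, `b`, `rmse`, `threshold`, `label`; row order equals
#' input order; numeric fields carry 15 significant digits.
#'
#' @param results An `ir_preclass` data.frame from [preclassify()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_preclass_tsv <- function(results, path) {
  stopifnot(is.data.frame(results))
  cols <- c("id", "a", "b", "rmse", "threshold", "label")
  df <- results[, cols, drop = FALSE]
  for (cc in c("a", "b", "rmse", "threshold"))
    df[[cc]] <- formatC(df[[cc]], digits = 15, format = "g")
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) ir_stop(
                    sprintf("cannot write '%s'", path), "ir_io_error"))
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Read back a preclassification TSV
#'
#' @param path TSV path written by [write_preclass_tsv()].
#' @return An `ir_preclass` data.frame.
#' @export
read_preclass_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("ir_preclass", "data.frame")
  df
}
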