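#' PCA scores of raw spectra
#'
#' Principal component scores for visual annotation of water vs cartilage
#' clusters. The spectra enter raw — no derivative, normalization or
#' scaling — and are only mean-centered, which is intrinsic to PCA; the
#' centering vector is returned so the step is auditable. The decomposition
#' is by SVD of the centered matrix. The sign of each component is fixed so
#' that its largest-magnitude loading is positive, making results
#' deterministic across runs and platforms.
#'
#' @param dataset An `ir_dataset` with at least 2 spectra.
#' @param k Number of components, `1 <= k <= min(n_spectra - 1, n_channels)`.
#' @param region Optional wavenumber interval(s) restricting the channels
#'   entering the PCA; default the full axis.
#' @return An object of class `ir_pca`: list with `scores` (n x k, rownames
#'   = ids), `explained_variance_fraction` (length k, non-increasing),
#'   `centering` (the subtracted mean spectrum over the used channels),
#'   `loadings` (n_channels_used x k) and `wavenumbers` (channels used).
#' @export
pca_scores <- function(dataset, k = 2L, region = NULL) {
  stopifnot(inherits(dataset, "ir_dataset"))
  n <- nrow(dataset$matrix)
  if (n < 2L)
    ir_stop("PCA needs at least 2 spectra", "ir_contract_error")
  idx <- region_indices(dataset$axis, region)
  p <- length(idx)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, p))
    ir_stop(sprintf("k = %d out of range [1, %d]", k, min(n - 1L, p)),
            "ir_contract_error")
  X <- dataset$matrix[, idx, drop = FALSE]
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc, nu = k, nv = k)
  # deterministic sign: largest-magnitude loading of each component positive
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1L))
  loadings <- sweep(sv$v, 2L, flip, `*`)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k, k), 2L, flip, `*`)
  rownames(scores) <- dataset$ids
  colnames(scores) <- paste0("PC", seq_len(k))
  total <- sum(sv$d^2)
  evf <- if (total > 0) sv$d[seq_len(k)]^2 / total else rep(0, k)
  structure(list(scores = scores,
                 explained_variance_fraction = evf,
                 centering = center,
                 loadings = loadings,
                 wavenumbers = dataset$axis[idx]),
            class = "ir_pca")
}

#' @export
print.ir_pca <- function(x, ...) {
  cat(sprintf("<ir_pca: %d spectra, %d components; explained %s>\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Advisory RMSE-threshold suggestion (Otsu split)
#'
#' The operative threshold theta is a user decision, made by inspecting
#' the broadband spectra; it is dataset dependent and no default is
#' shipped. As an *advisory* aid this helper returns the split of the RMSE
#' values that maximizes the between-class variance (Otsu's criterion,
#' computed exhaustively over all splits of the sorted values), together
#' with a histogram of the values for visual confirmation of bimodality.
#'
#' @param rmse_values Numeric vector of at least 4 RMSE values.
#' @param bins Histogram bin count for the diagnostics (does not affect the
#'   suggestion).
#' @return An object of class `ir_threshold_suggestion`: list with
#'   `threshold` (midpoint between the two classes at the optimal split),
#'   `between_class_variance`, `histogram` (a `hist`-style list),
#'   `no_split` (`TRUE` when all values are identical, with a warning) and
#'   `advisory = TRUE`.
#' @export
suggest_threshold <- function(rmse_values, bins = 32L) {
  x <- as.numeric(rmse_values)
  if (length(x) < 4L)
    ir_stop("at least 4 RMSE values required", "ir_contract_error")
  if (anyNA(x) || any(!is.finite(x)))
    ir_stop("non-finite RMSE values", "ir_contract_error")
  xs <- sort(x)
  n <- length(xs)
  h <- graphics::hist(xs, breaks = bins, plot = FALSE)
  if (max(xs) - min(xs) <= 0) {
    warning("all RMSE values identical; no split exists")
    return(structure(list(threshold = xs[1L],
                          between_class_variance = 0,
                          histogram = h, no_split = TRUE, advisory = TRUE),
                     class = "ir_threshold_suggestion"))
  }
  # exhaustive Otsu over the n-1 splits of the sorted values: maximize
  # w0*w1*(m0-m1)^2 via cumulative sums
  csum <- cumsum(xs)
  i <- seq_len(n - 1L)
  m0 <- csum[i] / i
  m1 <- (csum[n] - csum[i]) / (n - i)
  bcv <- (i / n) * ((n - i) / n) * (m0 - m1)^2
  best <- which.max(bcv)                       # ties -> lower split
  thr <- (xs[best] + xs[best + 1L]) / 2
  structure(list(threshold = thr,
                 between_class_variance = bcv[best],
                 histogram = h, no_split = FALSE, advisory = TRUE),
            class = "ir_threshold_suggestion")
}

#' @export
print.ir_threshold_suggestion <- function(x, ...) {
  cat(sprintf("<ir_threshold_suggestion (advisory): theta = %.6g%s>\n",
              x$threshold, if (x$no_split) " [no split]" else ""))
  invisible(x)
}
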