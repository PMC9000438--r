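#' Plot a spectrum
#'
#' Base-graphics absorbance trace; by IR convention the wavenumber axis is
#' displayed decreasing left to right (display only — computation always
#' uses the ascending canonical order).
#'
#' @param x An `ir_spectrum`.
#' @param reverse_x Display the axis conventionally reversed.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ir_spectrum <- function(x, reverse_x = TRUE, ...) {
  xlim <- range(x$wavenumbers)
  if (reverse_x) xlim <- rev(xlim)
  graphics::plot(x$wavenumbers, x$absorbance, type = "l", xlim = xlim,
                 xlab = expression(paste("wavenumber (", cm^-1, ")")),
                 ylab = "absorbance", main = x$id, ...)
  invisible(x)
}

#' Scatter plot of PCA scores
#'
#' @param pca An `ir_pca` from [pca_scores()].
#' @param labels Optional per-spectrum labels used for point color.
#' @param components Two component indices to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_pca_scores <- function(pca, labels = NULL, components = c(1L, 2L), ...) {
  stopifnot(inherits(pca, "ir_pca"))
  s <- pca$scores[, components, drop = FALSE]
  col <- if (is.null(labels)) "black"
         else as.integer(factor(labels)) + 1L
  graphics::plot(s[, 1L], s[, 2L], col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1L],
                                100 * pca$explained_variance_fraction[components[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2L],
                                100 * pca$explained_variance_fraction[components[2L]]),
                 ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))) + 1L, pch = 19)
  invisible(pca)
}
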