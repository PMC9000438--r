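#' First derivative of a spectrum with respect to wavenumber
#'
#' Central finite differences on interior channels and one-sided differences
#' at the two ends; the axis need not be uniformly spaced.
#'
#' @param spectrum An `ir_spectrum` with at least 3 channels.
#' @return An `ir_spectrum` holding dA/d(nu) (absorbance per cm^-1) on the
#'   same axis.
#' @export
first_derivative <- function(spectrum) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  x <- spectrum$wavenumbers
  y <- spectrum$absorbance
  n <- length(x)
  if (n < 3L)
    ir_stop("first derivative needs at least 3 channels", "ir_contract_error")
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
  ir_spectrum(x, d, id = spectrum$id)
}

#' First-derivative signal-to-noise statistic
#'
#' Signal is the peak-to-peak (max minus min) of the first derivative over
#' the signal region, by default 920-1200 cm^-1 (polysaccharide-associated
#' absorbance); Noise is the same statistic over the noise region, by
#' default 2000-2100 cm^-1, which is free of analyte bands. The ratio
#' Signal/Noise ranks spectra by analyte content; region endpoints are
#' inclusive.
#'
#' @param spectrum An `ir_spectrum` whose axis covers both regions with at
#'   least 3 channels each.
#' @param signal_region `c(lo, hi)` in cm^-1; default `c(920, 1200)`.
#' @param noise_region `c(lo, hi)` in cm^-1; default `c(2000, 2100)`.
#' @return An object of class `ir_snr`: list with `signal`, `noise`,
#'   `ratio` (`NA` when noise is exactly zero, flagged by
#'   `ratio_defined = FALSE`), `ratio_defined` and `regions`.
#' @export
snr <- function(spectrum, signal_region = c(920, 1200),
                noise_region = c(2000, 2100)) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  axis <- spectrum$wavenumbers
  for (rg in list(signal = signal_region, noise = noise_region)) {
    if (min(rg) < min(axis) || max(rg) > max(axis))
      ir_stop(sprintf("region [%.6g, %.6g] cm-1 outside the spectrum axis [%.6g, %.6g]",
                      min(rg), max(rg), min(axis), max(axis)),
              "ir_range_error")
  }
  d <- first_derivative(spectrum)
  ptp <- function(rg) {
    idx <- region_indices(axis, rg)
    if (length(idx) < 3L)
      ir_stop(sprintf("region [%.6g, %.6g] cm-1 holds %d channels; at least 3 required",
                      min(rg), max(rg), length(idx)), "ir_region_error")
    v <- d$absorbance[idx]
    max(v) - min(v)
  }
  sig <- ptp(signal_region)
  noi <- ptp(noise_region)
  structure(list(signal = sig, noise = noi,
                 ratio = if (noi > 0) sig / noi else NA_real_,
                 ratio_defined = noi > 0,
                 regions = list(signal = sort(signal_region),
                                noise = sort(noise_region)),
                 id = spectrum$id),
            class = "ir_snr")
}

#' @export
print.ir_snr <- function(x, ...) {
  cat(sprintf("<ir_snr '%s': signal %.4g, noise %.4g, ratio %s>\n",
              x$id, x$signal, x$noise,
              if (x$ratio_defined) sprintf("%.4g", x$ratio) else "undefined"))
  invisible(x)
}

#' Signal-to-noise table for a dataset
#'
#' Applies [snr()] to every spectrum of a dataset.
#'
#' @param dataset An `ir_dataset`.
#' @inheritParams snr
#' @return A data.frame with columns `id`, `signal`, `noise`, `ratio`
#'   (one row per spectrum, input order; `ratio` is `NA` where undefined).
#' @export
snr_table <- function(dataset, signal_region = c(920, 1200),
                      noise_region = c(2000, 2100)) {
  stopifnot(inherits(dataset, "ir_dataset"))
  rows <- lapply(seq_along(dataset$ids), function(i) {
    r <- snr(get_spectrum(dataset, i), signal_region, noise_region)
    data.frame(id = r$id, signal = r$signal, noise = r$noise,
               ratio = r$ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
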