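#' Default broadband ATR-FTIR wavenumber axis
#'
#' 400-4000 cm^-1 at a digital spacing of 1.0292 cm^-1, the grid of a
#' globar-source ATR-FTIR bench, so synthetic channel counts are realistic.
#'
#' @param from,to Axis limits in cm^-1.
#' @param by Digital spacing in cm^-1.
#' @return Numeric ascending wavenumber vector.
#' @export
default_axis <- function(from = 400, to = 4000, by = 1.0292) {
  seq(from, to, by = by)
}

#' Gaussian band models
#'
#' `water_bands()` describes the water absorbance profile in the
#' fingerprint region: flat except for broad bands near 1630 cm^-1 (OH
#' bending) and 800 cm^-1 (libration). `cartilage_bands()` describes the
#' analyte profile: lipid C=O at 1745, amide I at 1620 (largest amplitude),
#' amide II at 1560, amide III at 1210, carbohydrate C-O at 1080 and a
#' water-libration-associated band at 850 cm^-1.
#'
#' @return A data.frame of class `ir_band_model` with columns `center`
#'   (cm^-1), `sigma` (Gaussian width, cm^-1) and `amplitude` (peak
#'   absorbance).
#' @export
water_bands <- function() {
  b <- data.frame(center = c(800, 1630), sigma = c(120, 60),
                  amplitude = c(0.6, 1.0))
  class(b) <- c("ir_band_model", "data.frame")
  b
}

#' @rdname water_bands
#' @export
cartilage_bands <- function() {
  b <- data.frame(center    = c(850, 1080, 1210, 1560, 1620, 1745),
                  sigma     = c(40, 30, 25, 30, 30, 15),
                  amplitude = c(0.30, 0.50, 0.45, 0.70, 1.00, 0.25))
  class(b) <- c("ir_band_model", "data.frame")
  b
}

validate_bands <- function(bands) {
  if (!all(c("center", "sigma", "amplitude") %in% names(bands)))
    ir_stop("band model needs columns center, sigma, amplitude",
            "ir_contract_error")
  if (any(bands$sigma <= 0) || any(bands$amplitude < 0))
    ir_stop("band widths must be > 0 and amplitudes >= 0",
            "ir_contract_error")
  bands
}

# sum of Gaussian bands evaluated on an axis
eval_bands <- function(axis, bands) {
  y <- numeric(length(axis))
  for (k in seq_len(nrow(bands)))
    y <- y + bands$amplitude[k] *
      exp(-(axis - bands$center[k])^2 / (2 * bands$sigma[k]^2))
  y
}

check_coverage <- function(axis) {
  if (min(axis) > 700 || max(axis) < 1900)
    ir_stop(sprintf("axis [%.6g, %.6g] cm-1 must cover at least 700-1900 cm-1",
                    min(axis), max(axis)), "ir_range_error")
}

#' Synthetic pure-water reference spectrum
#'
#' Noise-free sum of the broad water Gaussians of [water_bands()]; flat
#' away from the two bands, as a measured water ATR spectrum is in the
#' fingerprint region.
#'
#' @param axis Wavenumber axis covering at least 700-1900 cm^-1.
#' @param bands Band model; default [water_bands()].
#' @return An `ir_spectrum` with id `"water_reference"`.
#' @export
water_reference <- function(axis, bands = water_bands()) {
  check_coverage(axis)
  validate_bands(bands)
  ir_spectrum(axis, eval_bands(axis, bands), id = "water_reference")
}

#' Synthetic cartilage spectrum
#'
#' Noise-free Gaussian-band cartilage profile; per-band multipliers allow
#' varying individual band intensities (all-zero multipliers give the zero
#' spectrum).
#'
#' @param axis Wavenumber axis covering at least 700-1900 cm^-1.
#' @param band_scale Per-band multipliers, one per row of `bands`.
#' @param bands Band model; default [cartilage_bands()].
#' @return An `ir_spectrum` with id `"cartilage"`.
#' @export
cartilage_spectrum <- function(axis, band_scale = rep(1, nrow(bands)),
                               bands = cartilage_bands()) {
  check_coverage(axis)
  validate_bands(bands)
  if (length(band_scale) != nrow(bands))
    ir_stop("one band_scale entry per band required", "ir_contract_error")
  b <- bands
  b$amplitude <- b$amplitude * band_scale
  ir_spectrum(axis, eval_bands(axis, b), id = "cartilage")
}

#' Simulate a labelled two-class spectral dataset
#'
#' Generates water-like rows `a + b * water_ref + noise` and cartilage-like
#' rows `a + b * water_ref + c * cartilage + noise`, emulating ATR probe
#' measurements where poor contact yields water-dominated (analyte-poor)
#' spectra and good contact adds the cartilage signature. Baselines `a`,
#' scalings `b` and cartilage fractions `c` are drawn uniformly from the
#' stated ranges; noise is i.i.d. Gaussian per channel. Fully deterministic
#' given `seed`: the same call regenerates the matrix bitwise.
#'
#' @param axis Wavenumber axis; default [default_axis()].
#' @param n_water,n_cartilage Row counts per class.
#' @param a_range,b_range,c_range Uniform ranges for baseline, scaling and
#'   cartilage fraction.
#' @param noise_sd Gaussian noise standard deviation (absorbance units),
#'   `>= 0`.
#' @param seed Integer RNG seed; required for reproducibility.
#' @param water_band_model,cartilage_band_model Band models used for the
#'   two pure components.
#' @return An object of class `ir_simulation`: list with `dataset` (an
#'   `ir_dataset`, water rows first), `truth` (data.frame with columns
#'   `id`, `class`, `a`, `b`, `c`, `noise_sd`), and `params` (everything
#'   needed to regenerate, see [regenerate()]).
#' @export
simulate_spectra <- function(axis = default_axis(),
                             n_water = 200L, n_cartilage = 200L,
                             a_range = c(-0.05, 0.05),
                             b_range = c(0.8, 1.2),
                             c_range = c(0.3, 1.0),
                             noise_sd = 0.005,
                             seed = 1L,
                             water_band_model = water_bands(),
                             cartilage_band_model = cartilage_bands()) {
  n_water <- as.integer(n_water); n_cartilage <- as.integer(n_cartilage)
  if (n_water < 0L || n_cartilage < 0L || n_water + n_cartilage < 1L)
    ir_stop("row counts must be >= 0 with at least one spectrum",
            "ir_contract_error")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    ir_stop("noise_sd must be >= 0", "ir_contract_error")
  check_coverage(axis)

  wref <- eval_bands(axis, validate_bands(water_band_model))
  cart <- eval_bands(axis, validate_bands(cartilage_band_model))
  n <- n_water + n_cartilage
  p <- length(axis)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  a <- stats::runif(n, a_range[1L], a_range[2L])
  b <- stats::runif(n, b_range[1L], b_range[2L])
  cc <- c(rep(0, n_water),
          stats::runif(n_cartilage, c_range[1L], c_range[2L]))
  noise <- matrix(stats::rnorm(n * p, sd = noise_sd), nrow = n)

  m <- outer(a, rep(1, p)) + outer(b, wref) + outer(cc, cart) + noise
  ids <- c(sprintf("water_%03d", seq_len(n_water)),
           sprintf("cartilage_%03d", seq_len(n_cartilage)))
  truth <- data.frame(id = ids,
                      class = rep(c("water", "cartilage"),
                                  c(n_water, n_cartilage)),
                      a = a, b = b,
                      c = ifelse(seq_len(n) > n_water, cc, NA_real_),
                      noise_sd = noise_sd, stringsAsFactors = FALSE)
  structure(list(dataset = ir_dataset(axis, m, ids = ids),
                 truth = truth,
                 params = list(axis = axis, n_water = n_water,
                               n_cartilage = n_cartilage,
                               a_range = a_range, b_range = b_range,
                               c_range = c_range, noise_sd = noise_sd,
                               seed = as.integer(seed),
                               water_band_model = water_band_model,
                               cartilage_band_model = cartilage_band_model)),
            class = "ir_simulation")
}

#' Regenerate a simulation from its stored parameters
#'
#' The stored parameters and seed fully determine the generated matrix;
#' regeneration reproduces it bitwise.
#'
#' @param sim An `ir_simulation` (or its `params` list).
#' @return A new `ir_simulation`, identical to the original.
#' @export
regenerate <- function(sim) {
  p <- if (inherits(sim, "ir_simulation")) sim$params else sim
  do.call(simulate_spectra, p)
}

#' Write simulation truth as TSV
#'
#' @param sim An `ir_simulation`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "ir_simulation"))
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
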