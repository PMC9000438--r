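---
title: "MSC-based preclassification of infrared spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSC-based preclassification of infrared spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irpreclass)
```

## The model and its assumptions

ATR measurements of hydrated tissue fail in a characteristic way: when
the probe-tissue contact is poor, the evanescent wave samples mostly the
surrounding water, and the recorded spectrum is an affine distortion of a
water spectrum rather than of the analyte. The preclassification model
exploits exactly this: each spectrum $Z(\tilde\nu)$ is regressed on a
reference spectrum with a constant and a scale,

$$Z(\tilde\nu) = a + b\,Z_{\mathrm{ref}}(\tilde\nu) + \varepsilon(\tilde\nu),$$

and the residual RMSE, $\sqrt{\tfrac1n\sum_i \varepsilon_i^2}$, gauges
dissimilarity to the reference. With a water reference, water-dominated
spectra are fit almost perfectly (RMSE at the noise floor) while
analyte-rich spectra leave their band structure in the residual. The
threshold rule is

$$\mathrm{RMSE} \le \theta \Rightarrow \text{water}, \qquad
  \mathrm{RMSE} > \theta \Rightarrow \text{cartilage},$$

with the boundary deliberately inclusive on the water side. The model
assumes only that (i) the matrix (water) signal enters each spectrum
affinely and (ii) the analyte signature is not itself an affine function
of the reference over the fit region — otherwise the residual cannot see
it. Higher-order polynomial wavenumber terms (the EMSC extension) are
deliberately not offered: on a seven-channel sparse axis the fit has
$n - 2 = 5$ residual degrees of freedom, and each extra term costs one
more; the two-parameter model is the one that transfers unchanged between
broadband and sparse axes.

The reference is a parameter. Water is the default and the recommended
choice: water spectra vary little (two broad bands in the fingerprint
region), whereas analyte spectra vary strongly between samples, which is
why an analyte reference separates poorly. Any `ir_spectrum` may be
supplied to `preclassify()` to explore that variant.

## Parameters that matter

* **Fit region** (cm⁻¹). Which channels enter the least squares is an
  explicit, required choice; the CLI defaults to 800–1900 cm⁻¹ — the
  fingerprint region where both the water bands and the analyte bands
  live — for broadband data and to the full given axis for sparse data.
  RMSE values are *not* comparable across regions or channel counts, so
  thresholds never transfer between axes: a broadband θ and a sparse θ
  must be chosen independently (with $n = 7$ the water-class RMSE is
  roughly an order of magnitude below a broadband value at the same
  noise, simply because the two fitted parameters absorb a larger share
  of 7 channels than of ~1000).
* **Threshold θ** (absorbance units). Dataset dependent; no default is
  shipped and the CLI refuses to run without one. `suggest_threshold()`
  offers an advisory Otsu split of the RMSE histogram, clearly labelled
  as an extension — on well-separated data it lands in the gap, but a
  wide analyte cluster can pull the variance-optimal split inside that
  cluster, which is why it is advisory and the operative choice stays
  with the analyst. For labelled (synthetic) data the package provides
  `gap_midpoint()`: when the two RMSE distributions are disjoint, the
  midpoint of the empty interval between them separates them perfectly;
  this is the deterministic reading of "a threshold between the two
  clusters" used throughout the tests.
* **Sparse channel set**. `miracle_channels()` returns the seven QCL
  wavenumbers (850, 1080, 1210, 1560, 1620, 1745, 1800 cm⁻¹: water
  libration, carbohydrate C–O, amide III, amide II, amide I, lipid C=O,
  and a baseline point). Matching is nearest-channel within a tolerance
  (default: one axis spacing), because fixed-wavelength QCL hardware
  emits at its lines rather than interpolating; ties break toward the
  lower wavenumber for determinism, and an interpolated pick is available
  behind `method = "interpolate"`. The out-of-range check allows
  `tolerance` slack at the axis ends so that re-selecting the nominal
  targets from an already-subset dataset is the identity (selection is a
  projection).
* **SNR regions**. Signal 920–1200 cm⁻¹ (polysaccharide-associated),
  noise 2000–2100 cm⁻¹ (free of analyte bands); both are parameters,
  endpoints inclusive.

## Annotation aids

The SNR statistic is the peak-to-peak of the *first derivative* in the
signal region over the same quantity in the noise region. The derivative
estimator is plain central finite differences (one-sided at the ends),
isolated behind `first_derivative()` so a smoothing estimator could be
swapped in; with no smoothing the statistic is exact on analytic test
spectra, at the cost of amplifying white noise by $\sigma\sqrt2/(2h)$ per
channel ($h$ = spacing). That amplification matters for interpretation:
at the generator's default noise ($\sigma = 0.005$) the derivative
peak-to-peak in both regions is noise-dominated and the ratio compresses
toward a constant, so the SNR ranking is informative in the
clean-acquisition regime ($\sigma \lesssim 0.001$ at 1 cm⁻¹-scale
spacing) and is exposed as a *ranking*, not a classifier — no SNR
threshold is shipped.

PCA scores are computed on raw spectra: no derivative, no normalization,
no scaling. Mean-centering is intrinsic to PCA and is applied; the
centering vector is returned so the step is auditable. The decomposition
is the SVD of the centered matrix; each component's sign is fixed by
making its largest-magnitude loading positive, so runs are deterministic.
The default two components match the 2-D score plots used for visual
annotation; PC1 of a two-cluster dataset separates the clusters when the
between-class difference dominates the within-class variance, but PCA is
a visual aid here, not an automated labeller.

## The synthetic generator

The generator exists so every property of the pipeline can be exercised
against known truth. It emulates the structure the method assumes:

* **Axis**: 400–4000 cm⁻¹ at 1.0292 cm⁻¹ digital spacing (a realistic
  FTIR bench grid, ~3500 channels).
* **Water**: two broad Gaussians, 1630 cm⁻¹ (σ = 60, amplitude 1.0) and
  800 cm⁻¹ (σ = 120, amplitude 0.6) — flat elsewhere in the fingerprint
  region.
* **Cartilage**: Gaussians at 1745, 1620, 1560, 1210, 1080 and 850 cm⁻¹
  with widths 15–40 cm⁻¹ and amide I (1620 cm⁻¹) the largest amplitude,
  mirroring the dominance of the protein backbone bands in connective
  tissue. Gaussian shapes (rather than Lorentzian/Voigt) are the simplest
  adequate choice for exercising an affine-fit-plus-residual method; the
  band model is a plain data.frame and fully configurable.
* **Distortions**: baseline $a \sim U(-0.05, 0.05)$, scaling
  $b \sim U(0.8, 1.2)$, cartilage fraction $c \sim U(0.3, 1.0)$, i.i.d.
  Gaussian channel noise with σ = 0.005 by default. These ranges produce
  the two-cluster RMSE structure the method is designed for: water rows
  concentrate at $\sigma\sqrt{1 - 2/n}$ (the exact expectation of the
  residual RMS after fitting two parameters to white noise) while
  cartilage rows sit an order of magnitude higher.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: correlated (pink) detector noise,
water-vapor and CO₂ interference lines, ATR penetration-depth dispersion,
scattering artifacts, and the biological variability of real cartilage
spectra (band shifts, varying band ratios). On real data the two RMSE
clusters need not be disjoint, which is precisely why θ is an
analyst-supplied, dataset-dependent parameter.

Determinism: all draws flow through one `set.seed(seed)` call (the
caller's RNG state is saved and restored), draws occur in a fixed order,
and the returned `params` regenerate the dataset bitwise via
`regenerate()`.

## Numerical choices

* The least-squares solve is closed-form: the reference is mean-centered
  internally, giving $b = \langle Z, r_c\rangle / \lVert r_c\rVert^2$ and
  $a = \bar Z - b\,\bar r$, then parameters are reported in the original
  $(a, b)$ parameterization. This is exact, fast (one matrix-vector
  product for a whole dataset), and avoids the conditioning loss of the
  raw normal equations.
* A reference that is constant over the fit region makes the design
  rank-deficient and is refused with an explicit error, as are regions
  with fewer than 3 channels (no residual degrees of freedom).
* The named "root mean squared error" carries the square root;
  $n$ is the channel count of the fit region.
* Resampling is linear interpolation with exact passthrough at shared
  channels and no extrapolation; linear is the minimal-assumption scheme
  and is exact for piecewise-linear inputs.
* Axes are strictly ascending internally everywhere; descending input
  files are canonicalized on read, and only display routines reverse the
  axis. This removes sign ambiguities from derivative and interpolation
  code.
* Degenerate inputs have defined behaviour: identical spectra give zero
  PCA scores and zero explained-variance fractions; identical RMSE
  values make `suggest_threshold()` warn and return that value; zero
  derivative noise makes the SNR ratio `NA` with `ratio_defined = FALSE`
  rather than an exception.
* CSV and TSV writers emit 15 significant digits so read/write round
  trips preserve values to ~1e-15 relative; JCAMP-DX support is limited
  to uncompressed AFFN tables (compressed ASDF dialects are refused with
  an explicit message), and vendor binary formats are out of scope.

## Problem sizes in the test suite

The suite validates solver exactness on 50-channel spectra against an
independent normal-equations oracle and 41×41 perturbation grids;
parameter recovery and class separation on 200 + 200 spectra × ~3500
channels across 20 seeds; and broadband/sparse concordance on the same
400-spectrum simulations subset to the seven QCL channels. These sizes
match the scale of a single-instrument clinical dataset (hundreds of
spectra) while keeping the full suite in the ten-second range.

## Known limitations

* Absolute RMSE thresholds are not transferable between instruments,
  fit regions, or axis densities; the package deliberately hard-codes
  none.
* The MSC residual cannot flag analyte spectra whose signature is
  (nearly) affine in the reference over the chosen region; widening the
  region is the remedy.
* The SNR statistic degrades with noisy, finely sampled axes (see
  above); pair it with the RMSE rule rather than using it alone.
* `suggest_threshold()` optimizes between-class variance, not the
  misclassification rate; with strongly unequal or wide clusters its
  split can fall inside a cluster. It is advisory by design.
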