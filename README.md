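# irpreclass

Preclassification of broadband and sparse infrared spectra by
multiplicative signal correction (MSC).

## The problem

In ATR infrared spectroscopy of hydrated tissue — e.g. arthroscopic
probing of articular cartilage — poor contact between the probe and the
tissue yields spectra dominated by the surrounding water or synovial
fluid. Such analyte-poor spectra carry no diagnostic information and must
be removed before any classification or regression model is built. On
broadband FTIR data (400–4000 cm⁻¹) an experienced operator can flag them
by eye; on sparse data from a handful of fixed-wavelength quantum cascade
lasers (QCLs), visual inspection is impossible and an automated rule is
required.

## The method

Every measured spectrum *Z*(ν̃) is modelled around a reference spectrum
*Z*<sub>ref</sub>(ν̃) — by default a pure water spectrum — with an additive
baseline *a* and a multiplicative scaling *b* (the MSC model):

&nbsp;&nbsp;&nbsp;&nbsp;*Z*(ν̃) = *a* + *b* · *Z*<sub>ref</sub>(ν̃) + *ε*(ν̃)

(*a*, *b*) are the ordinary least-squares solution over a chosen fit
region. The residual root mean squared error,

&nbsp;&nbsp;&nbsp;&nbsp;RMSE(*ε*) = √( Σᵢ *ε*ᵢ² / *n* ),

measures how well the water model explains the spectrum. Given a
dataset-dependent threshold θ:

&nbsp;&nbsp;&nbsp;&nbsp;RMSE ≤ θ → water (analyte-poor); RMSE > θ → cartilage (analyte-rich).

Because the rule uses only the per-channel residual, it applies unchanged
to a sparse axis: the package ships the seven-wavenumber QCL set
(850, 1080, 1210, 1560, 1620, 1745, 1800 cm⁻¹) and a nearest-channel
subsetter emulating fixed-line acquisition. Two annotation aids support
the choice of θ: a first-derivative signal-to-noise statistic
(peak-to-peak of the derivative at 920–1200 cm⁻¹ over that at
2000–2100 cm⁻¹) and PCA score plots of the raw spectra. A labelled
synthetic generator (water + cartilage Gaussian band models, affine
distortions, white noise) makes the whole pipeline testable end to end.

## Worked example

```r
library(irpreclass)

sim <- simulate_spectra(n_water = 30, n_cartilage = 30, seed = 42)
ref <- water_reference(sim$dataset$axis)
res <- preclassify(sim$dataset, ref, threshold = 0.03, region = c(800, 1900))
table(res$label)
#> cartilage     water
#>        30        30
head(res, 3)
#>                  id        a     b     rmse threshold label
#> water_001 water_001  0.04171 1.070 0.004918      0.03 water
#> water_002 water_002  0.04363 1.193 0.005046      0.03 water
#> water_003 water_003 -0.02138 1.105 0.005103      0.03 water
```

Each row reports the fitted baseline `a`, scaling `b`, and the residual
RMSE against the water reference; water-like rows sit at the noise floor
(here ≈ 0.005, the simulated noise level) while cartilage-like rows land
an order of magnitude higher, so any θ in the gap (here 0.03) separates
the classes exactly. The annotation aids:

```r
snr(get_spectrum(sim$dataset, "cartilage_001"))
#> <ir_snr 'cartilage_001': signal 0.02777, noise 0.01981, ratio 1.402>
suggest_threshold(res$rmse)   # advisory Otsu split of the RMSE values
#> <ir_threshold_suggestion (advisory): theta = 0.0823095>
```

The same pipeline is available from the shell via the installed
`exec/irpreclass` script:

```sh
irpreclass pipeline --simulate --seed 1 --synthetic-water \
    --auto-threshold --out run1
```

which writes the broadband and sparse result tables, SNR table, PCA
scores, a broadband/sparse concordance report and a `config.json` copy of
the resolved options; identical configurations give byte-identical
outputs.

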