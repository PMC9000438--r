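Package: irpreclass
Title: Preclassification of Broadband and Sparse Infrared Spectra by
    Multiplicative Signal Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality preclassification of ATR-FTIR absorbance spectra
    before diagnostic modelling. Each spectrum is fit to a water reference
    with an additive baseline and a multiplicative scaling (the
    multiplicative signal correction model); the residual root mean
    squared error is thresholded to separate analyte-poor (water-like)
    from analyte-rich (e.g. cartilage) spectra. Works identically on
    broadband axes and on sparse discrete-wavenumber subsets emulating
    fixed-wavelength quantum cascade laser acquisition. Includes
    first-derivative signal-to-noise and PCA score annotation aids, a
    labelled synthetic spectrum generator, CSV/JCAMP-DX input and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
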