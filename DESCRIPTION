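Package: irglucose
Title: Mid-Infrared Spectroscopic Glucose Quantification by PLS Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric pipeline for quantifying glucose in biofluids from
    mid-infrared (1200-925 cm-1) absorbance spectra. Implements spectral
    preprocessing (Savitzky-Golay smoothing and derivatives, Blackman-Harris
    Fourier low-pass filtering, baseline correction, vector normalisation),
    single-response partial least-squares regression (NIPALS), grouped
    holdout / leave-one-out / random-subset cross-validation with an
    exhaustive preprocessing-by-latent-variable grid search, and MAPE-based
    evaluation. A forward simulator generates transmission- and attenuated
    total reflection (ATR)-mode cohorts of glucose-in-matrix spectra so the
    whole analysis is exercisable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
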