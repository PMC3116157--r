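Package: unfoldfit
Title: Equilibrium Chemical Denaturation Analysis with Two- and Three-State
    Linear Extrapolation Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits guanidine hydrochloride induced equilibrium unfolding curves
    monitored by tryptophan fluorescence emission maxima to two-state (N-U) and
    three-state (N-I-U) models under the linear extrapolation method, with
    covariance- or bootstrap-based parameter uncertainties and AICc model
    selection. Extracts emission-maximum wavelengths from raw spectra, derives
    per-variant unfolding free energies (dG_NU) and mutation-induced stability
    changes (ddG_NU) relative to a reference protein, classifies destabilizing
    mutations, and compares experimental ddG values against structure-based
    predictor output. Includes a seeded synthetic-data generator for transition
    curves and emission spectra, including the published thermodynamic
    parameter panel for the Pro237 mutants of human carbonic anhydrase II.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
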