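Package: badgerlm
Title: Honey-Badger-Optimised Extreme Learning Machines for SWIR Spectral Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiclass classification of short-wave infrared (SWIR,
    1000-2500 nm) reflectance spectra, built around an Extreme Learning Machine
    (ELM) whose input weights and hidden biases are tuned by the Honey Badger
    Algorithm (HBA) and its adaptive t-distribution mutation variant (tHBA).
    Includes reflectance calibration against white/dark references, the standard
    scatter-correction preprocessing treatments (multiplicative scatter
    correction, standard normal variate, per-spectrum min-max normalisation),
    a real-coded genetic algorithm baseline optimiser, macro-averaged
    one-vs-rest evaluation metrics, a synthetic generator for pesticide-residue
    style melon spectra, and an end-to-end experiment pipeline with a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
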