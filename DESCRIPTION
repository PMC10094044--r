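Package: sdms
Title: Stochastic-Dynamic Processing of Scan-Level Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for quantitative and structure-oriented processing of
    scan-level mass-spectrometric data. Computes stochastic-dynamic diffusion
    parameters from per-scan intensity fluctuations over short spans of scan
    time, fits sine-squared temporal models, groups m/z measurands into
    statistically homogeneous (tautomer-resolved) subsets, builds
    concentration calibration models on the diffusion parameters, relates
    collision energy to theoretical ion intensities, evaluates a
    quantum-chemical diffusion parameter from ground- and transition-state
    vibrational data, and annotates adduct, fragment and isotope-pattern m/z
    values from elemental compositions. Includes a seeded synthetic
    scan-series generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mclust,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
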