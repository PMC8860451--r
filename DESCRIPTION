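Package: ramptime
Title: Analysis of Ramping Neural Signals in Self-Timed Movement Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing fiber-photometry recordings from self-timed
    movement experiments: synthetic session generation with known ground truth,
    fluorescence conditioning (four dF/F baseline methods with distortion
    diagnostics), hazard-function analysis of response-time distributions,
    nested ridge-regularised encoding and decoding generalised linear models,
    single-trial ramp-versus-step Bayesian classification by importance
    resampling, logistic movement-state hazard decoding, and resampling
    statistics for optogenetic perturbations. All stages operate on tidy trial
    tables and return tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Matrix,
    methods,
    jsonlite,
    readr,
    arrow,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
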