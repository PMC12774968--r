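Package: voleCMR
Title: Robust-Design Capture-Mark-Recapture Analysis of an Avian-Predation
    Exclusion Experiment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating apparent survival and population size of
    small mammals from robust-design live-trapping data, built around the
    Huggins conditional likelihood with random temporary emigration. Includes
    a synthetic-data generator with known truth, latent-class body-mass
    trajectory imputation by finite Gaussian mixtures, AICc model ranking and
    simulation-based multimodel averaging with percentile intervals and
    p-values, Horvitz-Thompson abundance, and parametric-bootstrap
    goodness-of-fit with overdispersion (c-hat) estimation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
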