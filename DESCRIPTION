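Package: densdep
Title: Density-Dependence Analysis of Annual Abundance Time Series
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting density dependence in annual abundance-index
    time series, built around the workflow used for declining monarch butterfly
    populations: log growth-rate construction with event-year exclusions and
    predictor standardization, maximum-likelihood fitting of Gaussian linear and
    site-level random-intercept models, AICc multi-model inference with Akaike
    weights and conditional model-averaged coefficients, and a stochastic
    Ricker/Gompertz population simulator for synthetic data and
    parameter-recovery experiments.
License: MIT + file LICENSE
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
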