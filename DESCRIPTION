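Package: phenocanopy
Title: Canopy Phenology from Time-Lapse Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts vegetation greenness indices (GCC, RCC, GEI, GGR, GRVI,
    HUE) from region-of-interest means of time-lapse canopy photographs, fits
    the double-logistic seasonal model to the resulting day-of-year series,
    locates phenological transition dates (start of season, maturity onset,
    senescence onset, end of season) at the extrema of the curvature change
    rate of the fitted curve, and forecasts the index with a gate-equation
    long short-term memory (LSTM) network trained on 30-day sliding windows.
    Includes a seeded synthetic-archive generator that emulates a camera
    archive with known ground truth, so every stage of the pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
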