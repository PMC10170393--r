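Package: spraintR
Title: Multi-Marker Fecal Metabarcoding Diet Analysis for Eurasian Otters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for presence-absence dietary analysis of a
    generalist predator from multi-marker fecal DNA metabarcoding and
    morphological prey remains. Implements negative-control and proportional
    read filtering of per-marker read tables, taxonomy-resolution-aware
    reconciliation of detections across markers and across molecular and
    morphological methods, construction of per-individual biotic and spatial
    covariates (scaled mass index via standardised major axis regression,
    Jenks natural-breaks size classes, river-distance and water-habitat
    assignment), prey-group aggregation with rarity filtering and occurrence
    statistics, and model-based multivariate analysis of diet composition
    using independent binomial complementary log-log GLMs per prey group with
    community likelihood-ratio statistics, parametric-bootstrap resampling
    inference, free step-down adjusted univariate p-values, and sum-AIC
    stepwise term selection. Ships a synthetic-data generator with known
    truth for end-to-end calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
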