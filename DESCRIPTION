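Package: fbnaug
Title: Spatial-Temporal Data Augmentation for Functional Brain Network Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for functional brain network (FBN) analysis from ROI-level
    resting-state fMRI time series under small-sample conditions. Implements
    spatial data augmentation by neighbour-set averaging over atlas geometry,
    temporal data augmentation by random discontinuous resampling of time
    points, Pearson-correlation network construction, dual-branch
    classification with tensor (outer-product) fusion of per-class score
    vectors (the STDAC scheme), leakage-safe stratified cross-validation of
    the original/SDA/TDA/STDAC schemes, discriminative-connection ranking from
    trained classifiers, and a synthetic-cohort generator with planted
    group-dependent correlation structure for validation without access to
    restricted clinical cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    MASS,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
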