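Package: mangrest
Title: Grid-Based Mangrove Habitat Suitability and Restoration Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, grid-based pipeline for assessing habitat
    suitability of true mangrove species and prioritizing restoration
    targets in coastal landscapes. Implements multi-algorithm ensemble
    species distribution modelling with explicit validation gates
    (Cohen's kappa, true skill statistic, ROC AUC, continuous Boyce
    index), spatial rarefaction of multi-source occurrence records,
    linear-SVM variable screening with average-merit scoring, niche
    overlap statistics (Schoener's D and the Hellinger-based I) with
    permutation significance, post-classification land-cover change
    accounting (degradation and accretion rates per grid), a human
    disturbance composite, and an indicator-based species-wise
    restoration prioritization algorithm. Ships a synthetic landscape
    generator with known ground truth so the whole pipeline is testable
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    MASS,
    nnet,
    rpart,
    randomForest,
    glmnet,
    xgboost,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
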