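Package: holdoutcca
Title: Regularized Canonical Correlation Analysis in a Multiple-Holdout
    Framework for Risk-Factor/Brain-Structure Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links many epidemiological risk factors to parcel-wise
    cortical structure with regularized canonical correlation analysis
    (RCCA) embedded in a multiple-holdout machine-learning framework.
    Provides leakage-free confound regression and brain-size scaling,
    hyperparameter selection by test canonical correlation and weight
    stability across inner splits, permutation tests with an omnibus
    decision over outer splits, deflation-based extraction of successive
    latent dimensions, stability-filtered loadings, spin-permutation
    spatial nulls for parcellated cortical maps, rank-based association
    of latent scores with external markers, and a calibrated synthetic
    cohort generator with planted ground truth for recovery testing.
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
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
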