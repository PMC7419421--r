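Package: cnaorigin
Title: Tumor Tissue-of-Origin Prediction from Gene-Level Copy Number Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage framework that predicts tumor tissue-of-origin from
    gene-level copy-number-alteration (CNA) profiles. A stacked symmetric
    autoencoder compresses GISTIC-style thresholded CNA vectors to a
    low-dimensional code, and a multi-scale one-dimensional convolutional
    network classifies samples from the code-layer features. The package
    includes readers for GISTIC-style matrices, cohort harmonization and
    max-absolute scaling, a synthetic segmental-CNA cohort simulator with a
    Bayes-optimal separability oracle, repeated stratified k-fold
    cross-validation with macro-averaged multiclass metrics, comparator
    classifiers (random forest, gradient boosting) with grid-search tuning,
    and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
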