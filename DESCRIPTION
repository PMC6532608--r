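Package: sigselect
Title: Automated Biomarker Signature Discovery by Exhaustive Model and
    Feature Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers predictive biomarker signatures in high-dimensional
    sample-by-feature tables (gene expression, proteomics, metabolomics,
    clinico-pathological data) by an exhaustive, criterion-optimised search
    over combinations of classifier, evaluation criterion and feature-subset
    search method. Features are first ranked by Information Gain
    (classification, with supervised entropy-minimisation discretisation) or
    ReliefF (regression); forward/backward stepwise selection with optional
    backward/forward elimination then optimises each classifier's feature
    subset by 10-fold cross-validation. Every candidate model is evaluated by
    cross-validation, leave-one-out, holdout, repeated holdout and bootstrap
    resampling plus the 0.632+ estimator, and the most stable model (best
    average MCC with low cross-procedure standard deviation) is selected.
    Ensemble vote classifiers, correlated-feature signature enrichment, an
    append-only CSV model registry with checkpoint/resume, and a synthetic
    omics-table generator with planted ground truth are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    MASS,
    e1071,
    rpart,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
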