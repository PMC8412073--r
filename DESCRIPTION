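Package: mnprofile
Title: Single-Cell Morphological Disease Profiling of Motor Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream statistical analysis of high-content microscopy
    feature tables of spinal motor neurons. Standardizes per-cell
    morphological measurements, decomposes them by singular value
    decomposition with explained-variance and spectrum-entropy accounting,
    associates principal components with disease phenotype contrasts via
    random-intercept linear mixed models, detects healthy/sick cell
    subpopulations with Gaussian mixture, logistic-regression and
    multi-layer-perceptron classifiers, aggregates per-cell disease
    probability and severity into per-animal scores compared by Welch's t
    test, decomposes classifiers into per-measurement relative
    contributions with category-level mixed-model and permutation tests,
    and ships a seeded synthetic-data generator emulating the assumed data
    structure so every stage is testable.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    glmnet,
    lme4,
    mclust,
    nnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
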