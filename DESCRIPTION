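Package: igenes
Title: Ensemble Biomarker Discovery with Concentration-Weighted Feature
    Attributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A case/control biomarker discovery pipeline for clinically
    integrated transcriptomic cohort tables. Combines four feature
    selectors (point-biserial correlation, chi-square score, one-way
    ANOVA, and random-forest recursive feature elimination), a
    seven-classifier prediction ensemble (random forest, SVM, XGBoost,
    k-nearest neighbours, multi-layer perceptron, soft and hard voting),
    and an I-Gene biomarker score that aggregates per-classifier additive
    feature attributions using Herfindahl-Hirschman concentration
    weights, with expression directionality labels. Includes a synthetic
    cohort simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
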