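Package: fsrml
Title: Feature Self-Recognition Machine Learning for Pulmonary Nodule Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for clinical risk prediction built around an
    improved sooty tern optimization algorithm (ISTOA) with Bernoulli-chaotic
    population initialization, Cauchy mutation of the incumbent best, and
    longitudinal-lateral (crisscross) crossover. The search runs over binary
    feature masks and scores each mask by the cross-validated accuracy of a
    pluggable base classifier (logistic regression, decision tree, k-nearest
    neighbours, feed-forward neural network, support vector machine, random
    forest, or gradient boosting). Includes the classical 23-function
    single-objective benchmark suite for optimizer comparison, confusion-matrix
    and ROC/PR evaluation metrics, univariate (chi-square, pooled t) and
    stepwise multivariable logistic statistics for cohort validation, a seeded
    synthetic physical-examination cohort generator with a 33-predictor schema,
    and a command-line front end for training, statistics, and per-subject risk
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    class,
    rpart,
    nnet,
    e1071,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
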