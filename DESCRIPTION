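Package: classbench
Title: Benchmark Comparisons of Classification and Feature-Selection
    Algorithms on Tabular Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A transparent benchmarking engine for classification and
    feature-selection algorithms on tabular biomedical data. Reads
    tab-separated, comma-separated and attribute-relation (ARFF) files,
    including transposed and gzip-compressed dialects, and merges multiple
    files on shared sample identifiers. Provides leakage-safe preprocessing
    (robust scaling, one-hot encoding, median/mode imputation), stratified
    Monte Carlo and k-fold cross-validation, nested cross-validation for
    hyperparameter selection and feature-subset-size search, a 15-metric
    evaluation suite computed one-versus-rest, Borda-count aggregation of
    per-fold feature rankings, and tidy tab-delimited outputs. Classifiers
    and feature rankers from established R packages are exposed behind a
    uniform adapter registry with declarative hyperparameter grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    foreign,
    yaml,
    withr,
    rpart,
    randomForest,
    ranger,
    xgboost,
    glmnet,
    e1071,
    kernlab,
    nnet,
    MASS,
    caret,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
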