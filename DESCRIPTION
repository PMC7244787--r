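Package: smurfens
Title: Hyper-Ensembles of SMOTE-Balanced Random Forests for Highly
    Imbalanced Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains and evaluates hyper-ensembles of random forests for
    binary classification problems with extreme class imbalance, such as
    the prioritization of pathogenic non-coding variants. The majority
    class is partitioned into disjoint parts; each part is joined with
    all minority examples, rebalanced by SMOTE oversampling of the
    minority class and uniform undersampling of the majority class, and
    used to train one random forest. Consensus scores are the average of
    the per-forest positive-class probabilities. Includes stratified and
    cytogenetic-band-aware cross-validation, per-region balanced
    subsampling, AUROC/AUPRC evaluation, exhaustive grid search and
    Gaussian-process Bayesian optimization of the six learning
    hyper-parameters, a synthetic imbalanced-data generator, and a
    JSON-configured command-line runner. Deterministic given a master
    seed regardless of the number of parallel workers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
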