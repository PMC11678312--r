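Package: combatcv
Title: Leakage-Safe ComBat Harmonization for Multi-Scanner Morphometry
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Empirical-Bayes location-scale (ComBat) harmonization of
    multi-scanner brain morphometry feature tables, embedded in a
    cross-validation framework that makes the harmonization fit-split
    explicit.  Provides a synthetic multi-scanner cohort generator with
    controllable scanner (batch) effects, group effects and scanner-group
    confounding; class balancing (SMOTE, random undersampling) and
    left-right flip augmentation applied to training folds only;
    stratified holdout and cross-validation splits; random hyperparameter
    search over standard classifier families; and scanner-specific
    evaluation reports.  The framework demonstrates how fitting the
    harmonization model with a diagnostic-group covariate leaks labels
    into the transformed features and inflates test AUC, while fitting on
    training folds only, without the group covariate, does not.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
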