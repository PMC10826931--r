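Package: emsflags
Title: Interpretable Keyword-Flag Classification of Opioid Overdoses in EMS Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and benchmarking lightweight, interpretable
    classifiers that identify opioid overdose events in emergency medical
    services (EMS) encounter records. Implements keyword "flag" feature
    engineering over six narrative fields (boundary-aware, case-insensitive
    counting of curated opioid and overdose term sets), TF-IDF and clinical
    concept-embedding comparison featurizers, four base learners (logistic
    GLM, single-hidden-layer neural network, naive Bayes, gradient-boosted
    trees) trained with repeated stratified cross-validation and random
    hyperparameter search, and a linear stacking ensemble fitted on
    out-of-fold probabilities. Evaluation utilities cover AUROC with DeLong
    variance and confidence intervals, confusion-matrix metrics,
    per-predictor importance, demographic parity tests, and intraclass
    correlation for annotation reliability. A seeded synthetic-cohort
    generator emulates EMS narratives with planted keyword signal and
    documented confounders, enabling fully reproducible benchmarks without
    protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    nnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
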