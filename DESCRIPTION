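Package: pepstack
Title: Stacked Ensemble Classification of Cytokine-Inducing Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for sequence-composition-based peptide classification,
    built around the problem of recognising interleukin-10 (IL-10) inducing
    MHC class II binders. Provides ten composition-type feature encoders
    (amino-acid, dipeptide, tripeptide and k-spaced pair compositions,
    pseudo and amphiphilic pseudo amino-acid composition, CTD composition,
    conjoint triad, Moran autocorrelation, reduced-alphabet composition),
    ADASYN and SMOTE oversampling for class imbalance, a stacking ensemble
    with five base learners and a logistic-regression meta-learner,
    stratified cross-validation and train/test evaluation with confusion
    metrics and ROC/AUC, a synthetic peptide generator with tunable class
    signal, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    rpart,
    e1071,
    class,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
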