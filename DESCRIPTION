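Package: stackrp
Title: Stacked Ensemble Prediction of Plant Disease-Resistance Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of plant disease-resistance (R)
    proteins. Protein sequences are encoded position-by-position with a
    fixed 20x20 residue pairwise contact-energy table, and two feature
    blocks are derived from the resulting L x 20 energy profile: multi-level
    discrete wavelet transform band statistics with leading discrete cosine
    coefficients (1040 features), and pseudo-positional features combining
    per-column means with lag correlations (20 + 20*lambda features).
    Features are ranked by support-vector-machine recursive feature
    elimination with correlation bias reduction (SVM-RFE+CBR), and a
    two-layer stacking classifier (KNN, gradient boosting, SVM, random
    forest and two further boosted-tree members feeding an SVM
    meta-classifier via out-of-fold probabilities) performs the final
    classification. Includes a synthetic sequence generator, stratified
    cross-validation with nested feature selection, and evaluation metrics
    (accuracy, precision, recall, F1, trapezoidal ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    class,
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
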