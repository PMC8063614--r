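Package: pmdfi
Title: miRNA-Disease Association Prediction via High-Order Feature
    Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ensemble prediction of miRNA-disease associations from
    similarity profiles. Builds Gaussian interaction profile (GIP) kernel
    similarities from a binary association matrix, MeSH-style DAG disease
    semantic similarity, greedy layer-wise stacked autoencoders that
    compress each similarity view into high-order features, pairwise
    cross features joining one miRNA-side and one disease-side view, and
    a stacking ensemble of four random forests combined by logistic
    regression. Includes cluster-balanced negative sampling, stratified
    cross-validation with AUC/AUPR/precision/recall/F1 reporting, a
    per-cross-feature ablation harness, candidate ranking per disease,
    and a block-structured synthetic data generator for end-to-end
    testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
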