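Package: kcrpred
Title: Sequence-Based Prediction of Lysine Crotonylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for predicting lysine crotonylation (Kcr) sites from
    protein sequence. Builds 31-residue peptide windows around annotated
    lysines, encodes them with seven sequence-based feature schemes (AAC,
    AAPC, binary encoding, CKSAAP, EAAC, EGAAC and sigmoid-normalised PSSM
    profiles), ranks feature dimensions by chi-square, gradient-boosted-tree
    importance or max-relevance-max-distance, and trains grid-searched
    SVM (RBF kernel) and random-forest classifiers evaluated by stratified
    ten-fold cross-validation, independent testing and cross-species
    transfer. Includes position-specific composition statistics and a seeded
    synthetic-data generator with controllable flanking-composition signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
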