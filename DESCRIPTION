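Package: ksinfer
Title: Substrate-Based Kinase Activity Inference from Phosphoproteomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers changes in kinase activity from site-level quantitative
    phosphoproteomic fold changes and a kinase-substrate network. Implements
    five inference statistics (one-sample Z-test, Kolmogorov-Smirnov test,
    Wilcoxon rank-sum test, a permutation-based enrichment score, and ridge
    multiple linear regression), sequence-specificity weighting of substrate
    fold changes via position weight matrices and MATCH-style matrix
    similarity scores, a ROC/precision-recall benchmarking harness with
    negative-pair sampling and degree-preserving network randomization, and a
    synthetic-data generator with embedded ground-truth kinase regulation for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
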