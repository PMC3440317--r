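Package: tripitope
Title: Linear B-Cell Epitope Prediction from Tri-Peptide Similarity and
    Propensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts linear B-cell epitopes on protein antigens with a
    support vector machine over a 20^3-dimensional tri-peptide attribute
    space. Each attribute combines a substitution-matrix (BLOSUM62 or
    PAM160) subsequence similarity kernel with a tri-peptide propensity
    scale estimated from known epitopes against a background protein
    pool. Includes similarity-aware five-fold cross-validation with
    redundancy reduction, grid search over SVM parameters, ROC/AUC
    evaluation with a paired DeLong test, attribute-weight extraction,
    a sliding-window predictor for full-length antigens, a virus-vs-human
    style tendency screen, and a synthetic-sequence generator that plants
    tri-peptide-enriched epitopes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
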