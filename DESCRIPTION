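Package: hatsite
Title: Prediction of Histone Acetyltransferase-Specific Lysine Acetylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which histone acetyltransferase (HAT) acetylates a given
    lysine residue, for seven well-characterized HATs (CREBBP, EP300, HAT1,
    KAT2A, KAT2B, KAT5, KAT8). A query peptide window around a lysine is scored
    by its mean substitution-matrix similarity to the known substrate peptides
    of each HAT (group-based prediction). Models are trained by a three-step
    stochastic procedure - exhaustive motif-length selection, position-weight
    training and substitution-matrix mutation under simulated annealing -
    maximizing leave-one-out sensitivity at fixed specificity. Includes ROC/AUC
    evaluation with leave-one-out and stratified k-fold cross-validation,
    specificity-calibrated prediction thresholds, acetylome-scale annotation
    summaries, reciprocal-best-hit ortholog screening to restrict models by
    species, and a planted-motif synthetic data generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
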