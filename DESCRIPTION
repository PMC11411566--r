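Package: lncBoost
Title: Boosted Multiclass Prediction of lncRNA Subcellular Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular localization of long non-coding RNAs
    (nucleus, cytoplasm, cytosol, ribosome, exosome) from primary sequence.
    Features combine overlapping trinucleotide (3-mer) frequencies, per-frame
    non-overlapping reading-frame triplet frequencies, and a minimum-free-energy
    scalar from a simplified Zuker-style secondary-structure fold (or imported
    RNAfold output). Class imbalance is addressed with Borderline-SMOTE and
    ADASYN oversampling plus an ensemble-uncertainty filter, and classification
    uses a multiclass AdaBoost variant whose round coefficient carries the
    SAMME log(k-1) correction. Includes F-score feature ranking, one-vs-rest
    performance metrics with ROC/AUC, stratified cross-validation with
    leakage-safe in-fold balancing, dot-bracket substructure (stem/loop/
    junction) triplet-frequency analysis, and a synthetic sequence generator
    with planted trinucleotide enrichments for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
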