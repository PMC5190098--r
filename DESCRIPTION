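Package: hydroxysite
Title: Sequence-Coupled Prediction of Protein Hydroxylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hydroxyproline and hydroxylysine sites in protein
    sequences from sequence-coupled conditional-probability features.
    Peptide windows centered on candidate Pro/Lys residues are encoded as
    the difference between positive-class and negative-class first-order
    neighbor-conditional probability vectors (a general pseudo amino acid
    composition mode) and classified with a random forest. Includes
    benchmark-dataset construction from annotated FASTA input (window
    extraction, X-padding, deduplication, self-conflict screening),
    jackknife and stratified k-fold evaluation with sensitivity,
    specificity, accuracy, Matthews correlation and ROC/AUC reporting,
    Gini-importance feature ranking, whole-protein site scanning, and a
    synthetic-data generator with known class-specific neighbor coupling
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
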