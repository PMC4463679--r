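Package: wsrcppi
Title: Protein-Protein Interaction Prediction with Reduced Amino Acid
    Alphabets and Weighted Sparse Representation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-based prediction of protein-protein interactions.
    Protein pairs are encoded as n-peptide composition vectors over
    reduced amino acid alphabets (cluster profiles derived from the
    protein blocks structural alphabet), and classified with a weighted
    sparse representation classifier: each query is sparse-coded against
    a Gaussian-kernel-weighted dictionary of training pairs by basis
    pursuit denoising, and assigned the class with the smallest
    class-restricted reconstruction residual.  Includes the standard
    evaluation harness (accuracy, sensitivity, precision, Matthews
    correlation coefficient, ROC/AUC) under stratified k-fold
    cross-validation, FASTA and pair-list input/output, a synthetic
    benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    glmnet,
    pROC,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
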