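Package: mosppi
Title: Matrix-of-Sequence Protein Descriptors for Protein-Protein
    Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein sequences as matrix-of-sequence (MOS)
    descriptors: residues are reduced to seven physicochemical groups, a
    7x7 ordered co-occurrence matrix is accumulated by a single linear
    scan, normalized, and flattened into a 29-dimensional feature vector
    (28 upper-triangle entries plus the reciprocal sequence length).
    Also provides the conjoint-triad, auto-covariance and local-descriptor
    comparison encoders, readers and filters for FASTA proteomes and
    two-column interaction pair lists, a synthetic proteome generator with
    a planted group-composition signal, a feed-forward neural network
    classifier trained by Adam on binary cross-entropy, classical
    classifier baselines, and repeated hold-out evaluation with accuracy,
    recall, ROC AUC and cross-entropy loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    jsonlite,
    randomForest,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
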