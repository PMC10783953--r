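Package: pepmhc
Title: Peptide-MHC Class I Binding Prediction with Sub-Word Sequence Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binding between peptide antigens and Class I major
    histocompatibility complex (MHC/HLA) proteins. Amino-acid sequences are
    split into fixed-width words and character sub-words; sub-word embeddings
    are pre-trained with a skip-gram objective using sequence windows (for
    peptides) and Calpha-distance thresholded structural contexts (for HLA
    alleles), then fed into a fully connected network that outputs a binding
    probability. Includes per-batch synthetic negative sampling for
    immunopeptidomics data, an IC50 affinity transform and transfer-learning
    mode, FDR-anchored evaluation metrics with low-data-allele and
    edit-distance stratifications, and a synthetic data generator for
    desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
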