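Package: resubinet
Title: Ubiquitination Site Prediction with the ResUbiNet Deep Learning
    Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of protein ubiquitination sites
    using the ResUbiNet architecture: lysine-centred window extraction,
    three-channel feature encoding (31 AAindex physicochemical
    properties, the BLOSUM62 substitution matrix, and a 1024-dimensional
    protein-language-model embedding), and a hybrid neural network
    combining multi-head self-attention, multi-kernel one-dimensional
    convolution, residual connections, and squeeze-and-excitation
    channel recalibration. Includes 5-fold cross-validation ensemble
    training with averaged-probability prediction, a window-length sweep
    experiment, a full binary-classification evaluation suite (accuracy,
    sensitivity, specificity, precision, F1, Matthews correlation
    coefficient, ROC and precision-recall areas), and sequence-pattern
    analyses of ubiquitinated versus non-ubiquitinated windows
    (amino-acid frequencies, two-sample-logo enrichment tests, and VHSE
    positional property profiles). A synthetic-data generator with
    planted flanking motifs and label-correlated embeddings supports
    fully offline end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
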