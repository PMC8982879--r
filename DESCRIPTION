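Package: strucr
Title: Alignment-Free Protein Structure Comparison with Contrastive Graph Encoders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Alignment-free comparison, retrieval and superposition of protein
    tertiary structures. Each single-chain structure is turned into a complete
    C-alpha graph with rotation- and translation-invariant node features
    (reference-point distances and bend-angle cosines), encoded by a
    BiLSTM + residual graph-convolution network into a fixed-length unit
    descriptor, and trained with a momentum-contrast framework: a
    momentum-updated key encoder, a FIFO queue of negative descriptors, an
    InfoNCE loss, and a dynamic training-data partition driven by TM-score
    supervision. Retrieval ranks databases by a length-scaling cosine
    distance; evaluation implements the structural-neighbor definition,
    per-query AUROC/AUPRC, Top-K hit ratio, a logistic-regression fold-class
    probe and a resampling significance test. Residue-level descriptors drive
    Needleman-Wunsch correspondence and Kabsch superposition. A synthetic
    C-alpha trace generator with a same-length TM-score oracle supports
    desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
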