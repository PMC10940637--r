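Package: molfusion
Title: Dual-Stream Multimodal Transformer for Molecular Structure and Property Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A structure-property multimodal molecular model that treats a
    fixed-order vector of molecular descriptors as a second language alongside
    SMILES. Two unimodal transformer encoders (one per modality) are aligned
    with a queue-based contrastive objective and fused by a weight-shared
    cross-attention encoder trained with next-word prediction on SMILES,
    next-property regression on descriptor vectors, and a matching head with
    hard-negative mining, using a momentum (EMA) teacher for soft pseudo-labels.
    The trained model generates SMILES conditioned on partial property vectors
    (greedy, stochastic or beam decoding), predicts full property vectors
    autoregressively from SMILES, exposes cross-attention maps between
    properties and SMILES subwords, and fine-tunes for scalar prediction and
    reaction seq2seq tasks. Includes a byte-pair-encoding SMILES tokenizer, an
    Open Babel backed descriptor registry, Bemis-Murcko scaffold splitting,
    and deterministic toy-corpus generators so the whole pipeline runs
    self-contained.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    igraph,
    ChemmineR,
    matrixStats,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Open Babel (the 'obabel' command-line tool)
Config/testthat/edition: 3
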