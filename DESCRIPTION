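Package: smiqsar
Title: Interpretable QSAR from SMILES via Seq2Seq Embeddings and Convolutional Heads
Version: 0.1.0
Authors@R: person("QSAR", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Character-level SMILES modelling toolkit: a sequence-to-sequence
    transformer trained to canonicalize SMILES strings, whose frozen encoder
    yields variable-length per-position embeddings; a convolutional (TextCNN)
    QSAR head trained on those embeddings with SMILES-enumeration augmentation
    and consensus inference; and a layer-wise relevance propagation engine that
    decomposes predictions into per-atom contributions with an explicit
    bias-dissipation ledger and applicability warning. Includes toolkit-free
    synthetic molecule generators so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
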