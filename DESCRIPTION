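Package: hgtlink
Title: Heterogeneous Graph Transformer Link Prediction for Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Knowledge-graph link prediction for drug repurposing with a
    heterogeneous graph transformer. Builds typed biomedical knowledge graphs
    from edge tables (PrimeKG-style CSV), filters drugs and diseases without
    indication support, masks a fraction of indication edges, encodes nodes
    with meta-relation-parameterised multi-head attention layers, samples
    type-budgeted mini-batch subgraphs, scores drug-disease pairs with a
    fully connected decoder, and trains the encoder and decoder end to end
    against a negative-sampling binary cross-entropy objective. Includes
    k-fold cross-validation, novel-pair ranking, relation-removal robustness,
    relation retargeting, a new-disease evaluation scenario, and a seeded
    synthetic knowledge-graph generator with planted indication structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
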