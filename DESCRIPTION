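Package: herbnet
Title: Heterogeneous Graph Attention Modelling of Multi-Herb Prescription Efficacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the therapeutic efficacy of multi-herb prescriptions from a
    heterogeneous network of prescriptions, botanical drugs, metabolites and protein
    targets. Herbs are encoded from their property/flavor/meridian attributes,
    molecules from SMILES via circular fingerprints and contrastive sequence
    embeddings, and node representations are learned with a relational graph
    attention network trained end-to-end through a built-in reverse-mode
    automatic-differentiation engine. Class imbalance is addressed by a generative
    adversarial network that synthesizes prescription nodes (label, feature and
    prescription-herb adjacency), pruned against classical herb-incompatibility
    rules before being merged into the training graph. Includes a synthetic-data
    generator with a planted efficacy rule, stratified cross-validation, ablation
    variants, and export of post-training attention weights for interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
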