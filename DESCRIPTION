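Package: molgcn
Title: Cost-Sensitive Graph Convolutional Networks for Multi-Task
    Molecular Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-task binary classification of chemical compounds from
    SMILES with a degree-indexed graph convolutional neural network and a
    focal-loss objective for heavily imbalanced label sets, as used for
    organ-Meridian annotation of herbal ingredient compounds. Provides
    SMILES-to-graph featurization and hashed circular (ECFP-style)
    fingerprints, four dataset splitting strategies (index, random,
    iterative multi-label stratified, Bemis-Murcko scaffold), ROC-AUC
    evaluation with per-task confusion matrices, a synthetic planted-motif
    molecule generator for benchmarking under controlled class imbalance,
    and an experiment runner with layer/width sweep presets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
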