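Package: kgsimgp
Title: Ontology-Based Semantic Similarity and Genetic-Programming Aspect
    Combination for Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-aspect semantic similarity between entities
    annotated to a multi-rooted is-a ontology (SimGIC and Resnik
    best-match-average / maximum variants over intrinsic, descendant-count
    information content) and evolves, with tree-based genetic programming,
    a readable combination of the aspect scores that classifies entity
    pairs, such as protein-protein interactions annotated with the Gene
    Ontology. Ships static single-aspect and average/maximum baselines
    with training-set threshold selection, an exhaustive weighted-average
    grid search, a decision-tree reference classifier, stratified
    cross-validation and cross-dataset protocols scored by the weighted
    average of per-class F-measures, and a synthetic-data generator
    (ontology, annotations, labeled pairs) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
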