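Package: drinfer
Title: Imbalance-Aware Classification and Candidate Inference of
    Dietary-Restriction-Related Ageing Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds heterogeneous feature datasets for ageing-related genes
    (pathway membership, ancestor-propagated Gene Ontology annotations,
    pathway-graph influence scores, protein-protein interaction adjacency and
    graph measures, continuous expression-style matrices), evaluates
    imbalance-aware tree-ensemble classifiers of dietary-restriction (DR)
    relatedness under nested cross-validation with training-fold-fitted
    preprocessing, quantifies feature importance and enrichment, and infers
    novel DR-candidate genes by false-positive ranking and cross-model score
    fusion. Includes a synthetic-data module that emulates the statistical
    structure of the curated sources so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
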