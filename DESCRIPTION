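Package: chondronet
Title: Semi-Quantitative Two-Layer Network Model of Chondrocyte Phenotype Switching
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and simulates two-layer (protein signaling + gene
    regulatory) network models of articular chondrocyte fate with a
    semi-quantitative additive formalism and priority-class asynchronous
    updating. Discovers attractors and their basins by Monte Carlo sampling,
    runs exhaustive single and pairwise in-silico perturbation screens with
    candidate-treatment selection, dose-grid experiments and Markov transition
    summaries, and provides a companion consensus gene-regulatory-network
    inference pipeline (mutual-information with DPI pruning, tree-ensemble
    importance, and stability-selection regression) with quantile
    normalization and empirical-Bayes batch correction for multi-batch
    expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    xml2,
    glmnet,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
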