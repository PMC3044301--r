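Package: hacnet
Title: Hierarchical Agglomerative Clustering and Link Prediction for
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood hierarchical agglomerative clustering of
    undirected interaction networks under a Bernoulli stochastic block
    model, with Bayesian model selection for collapsing homogeneous
    bottom-level clusters and for identifying top-level clusters.  Model
    scores are additive over independent edge types, enabling joint
    clustering of multiple interaction layers.  Includes heuristic merge
    scores (edge density, shared-neighbour density, decomposed Newman
    modularity), a cross-validated missing-link prediction harness with
    precision/recall, F-score and AUC, synthetic planted-partition and
    hierarchical-random-graph generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
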