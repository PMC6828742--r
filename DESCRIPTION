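Package: netbite
Title: Network-Based Biased Tree Ensembles for Drug Sensitivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression tree ensembles whose per-node candidate-feature
    subsets are drawn with probabilities proportional to prior-knowledge
    bias weights (BiTE), together with random-walk network propagation of
    drug-target weights over a protein-protein interaction network
    (NetBiTE). Includes a synthetic drug-sensitivity benchmark generator,
    a cross-validation evaluation harness with paired model comparisons
    and control experiments, readers for STRING-style edge lists and
    expression matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ranger,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
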