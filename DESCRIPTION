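Package: infinet
Title: Three-State Spin Cascades, Google-Matrix Ranking and Erdos Barrage on Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates fibrosis-like activation cascades on directed
    protein-protein interaction networks with a three-state (+1/0/-1) spin
    model driven by an asynchronous Monte Carlo process with permanently
    fixed activator ("red") and repairing ("blue") nodes. Provides
    matrix-free PageRank and CheiRank computation on the Google matrix,
    extraction of the Erdos-1 candidate set around the activated hub,
    ranking of single-node and multi-node blue "barrage" interventions by
    conditional red outcome, distributional summaries of per-node outcome
    fractions (histograms, complementary CDF tails, power-law tail fits),
    and a synthetic scale-free network generator so that every stage is
    testable without proprietary network data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
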