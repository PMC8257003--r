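Package: lingnet
Title: Bayesian Agent-Based Simulation of Language Change on Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the spread and stabilization of a binary linguistic
    variant in a population of Bayesian Beta-Bernoulli agents communicating
    over random, small-world, or scale-free networks. Agents hold a Beta
    belief over the frequency of the variant, update it conjugately from
    utterances broadcast by network neighbors, and produce utterances by
    sampling from the posterior (SAM) or by using its mode (MAP). A
    configurable fraction of agents carries an intrinsic prior bias of
    tunable location and strength, optionally concentrated on the most
    central ("influencer") nodes. The package computes the outcome
    statistics of such simulations: group language values, the
    unbiased-minus-biased difference, between-community heterogeneity over
    Louvain communities, and sliding-window stabilization times, and
    provides a replicated parameter-sweep runner with aggregation, isoline
    extraction, rank-sum helpers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
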