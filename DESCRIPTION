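Package: wcne
Title: Well-Controlling Network Ensembles for Topologically Targeted
    Social Distancing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for designing link-removal (social distancing)
    interventions on contact networks by targeting the spectral radius of
    the adjacency matrix, whose inverse approximates the SIS epidemic
    threshold. Samples the canonical "well-controlling network ensemble"
    of fixed-edge-count subgraphs weighted by exp(-nu * lambda_max) with a
    Metropolis-Hastings edge-swap sampler, implements degree-homogenizing
    removal heuristics (degree product, degree cap) and an
    edge-betweenness baseline, and verifies threshold shifts with
    discrete-time SIS/SIR simulations and beta/delta tipping-point scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
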