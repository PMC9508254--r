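Package: crownet
Title: Tree Competition Networks and Spatial Null Models for Forest Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds individual-tree competition networks from stem maps and
    marked point patterns: a fixed-radius competition-for-space graph, a
    crown-overlap competition-for-light graph, and a directed, weighted
    variant whose edge weights are a crown-overlap competition index.
    Provides simulators for five spatial null models (complete spatial
    randomness, Matern and Thomas cluster processes, Gibbs hard-core and
    Strauss inhibition processes), second-order point-pattern statistics
    (Ripley's K, Besag's L, the pair correlation function) with Monte-Carlo
    simulation envelopes, and a validation workflow that decides which
    network metrics can distinguish the underlying spatial processes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    fitdistrplus,
    ggplot2,
    igraph,
    mgcv,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
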