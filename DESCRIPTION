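Package: symptomnet
Title: Cross-Sectional and Temporal Network Analysis of Ordinal Symptom Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and comparison of psychopathology symptom networks
    from short ordinal panel data such as repeated Young Mania Rating Scale
    (YMRS) assessments. Provides cross-sectional Gaussian graphical models
    (partial correlation networks) from Spearman or Pearson input, with and
    without EBIC graphical-lasso regularization; node predictability (per-node
    shared variance); global strength and strength centrality; bootstrap
    edge-accuracy and case-drop stability analyses with the
    correlation-stability coefficient; a permutation Network Comparison Test
    for global-strength invariance between paired or independent samples; a
    pooled least-squares panel graphical vector autoregression giving a
    Granger-causal temporal network with a contemporaneous residual network;
    and a latent-Gaussian synthetic panel generator with known network
    structure for validation. Networks export as labeled CSV, edge lists,
    GraphML and JSON.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
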