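test_that("precision-to-partial-correlation follows the closed forms", {
  expect_equal(precision_to_pcor(diag(3)), matrix(0, 3, 3))
  K <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(precision_to_pcor(K)[1, 2], 0.5)

  # equicorrelation 0.5 triple: recursion-formula oracle gives every edge
  C <- matrix(0.5, 3, 3)
  diag(C) <- 1
  r <- 0.5
  pcor_12_3 <- (r - r * r) / sqrt((1 - r^2) * (1 - r^2))
  W <- precision_to_pcor(solve(C))
  expect_equal(unname(W[upper.tri(W)]), rep(pcor_12_3, 3), tolerance = 1e-12)
  expect_equal(pcor_12_3, 1 / 3)

  expect_error(precision_to_pcor(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(precision_to_pcor(matrix(1:4, 2)), "symmetric")
})

test_that("nonregularized GGM equals the nodewise-regression oracle", {
  set.seed(31)
  for (rep in 1:25) {
    C <- rand_pd_cor(11)
    net <- estimate_ggm(C, n = 100)
    expect_lt(max(abs(net$weights - pcor_nodewise_oracle(C))), 1e-8)
  }
})

test_that("predictability equals brute-force OLS R^2", {
  # p = 2: R^2 = r^2
  C2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(unname(node_predictability(C2, n = 50)), c(0.36, 0.36))
  # identity: all zero
  expect_equal(unname(node_predictability(diag(4), n = 50)), rep(0, 4))
  # equicorrelation 0.5 triple: r' R^-1 r oracle
  C3 <- matrix(0.5, 3, 3)
  diag(C3) <- 1
  expect_equal(unname(node_predictability(C3, n = 50)),
               r2_ols_oracle(C3), tolerance = 1e-12)
  expect_equal(unname(node_predictability(C3, n = 50)), rep(1 / 3, 3),
               tolerance = 1e-12)
  # random matrices
  set.seed(77)
  for (rep in 1:25) {
    C <- rand_pd_cor(11)
    expect_lt(max(abs(node_predictability(C, n = 100) - r2_ols_oracle(C))),
              1e-8)
  }
})

test_that("node relabeling permutes all outputs consistently", {
  set.seed(5)
  C <- rand_pd_cor(6)
  dimnames(C) <- list(letters[1:6], letters[1:6])
  perm <- c(4, 2, 6, 1, 3, 5)
  Cp <- C[perm, perm]
  net <- estimate_ggm(C, n = 60)
  netp <- estimate_ggm(Cp, n = 60)
  expect_equal(netp$weights, net$weights[perm, perm], tolerance = 1e-12)
  expect_equal(node_predictability(Cp, n = 60),
               node_predictability(C, n = 60)[perm], tolerance = 1e-12)
  expect_equal(strength_centrality(netp), strength_centrality(net)[perm],
               tolerance = 1e-12)
  expect_equal(global_strength(netp), global_strength(net),
               tolerance = 1e-12)
})

test_that("strength descriptives follow their arithmetic definitions", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- -0.2
  net <- structure(list(weights = W, nodes = letters[1:4],
                        method = "nonregularized",
                        input_correlation = "spearman", n = 50,
                        lambda_selected = NA, gamma = NA),
                   class = "network_model")
  expect_equal(global_strength(net), 0.5)
  expect_equal(unname(strength_centrality(net)), c(0.5, 0.3, 0.2, 0))
  # handshake identity
  expect_equal(sum(strength_centrality(net)), 2 * global_strength(net))
  # empty network
  empty <- estimate_ggm(diag(5), n = 50)
  expect_equal(global_strength(empty), 0)
  expect_equal(unname(strength_centrality(empty)), rep(0, 5))
  # 11 nodes sum over 55 pairs
  set.seed(8)
  C <- rand_pd_cor(11)
  net11 <- estimate_ggm(C, n = 100)
  expect_equal(global_strength(net11),
               sum(abs(net11$weights)) / 2, tolerance = 1e-12)
  expect_length(net11$weights[upper.tri(net11$weights)], 55)
})

test_that("display filtering drops weak edges without touching the model", {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W[1, 2] <- W[2, 1] <- 0.05
  W[1, 3] <- W[3, 1] <- 0.15
  W[2, 3] <- W[3, 2] <- -0.2
  net <- structure(list(weights = W, nodes = c("a", "b", "c"),
                        method = "nonregularized",
                        input_correlation = "spearman", n = 40,
                        lambda_selected = NA, gamma = NA),
                   class = "network_model")
  kept <- display_filter(net, 0.1)
  expect_equal(nrow(kept), 2)
  expect_false(any(kept$weight == 0.05))
  expect_equal(nrow(display_filter(net, 0)), 3)
  expect_equal(net$weights, W)  # unchanged
  expect_error(display_filter(net, -0.1))
})

test_that("Fisher-z edge screen keeps strong edges and nothing at alpha 0", {
  set.seed(12)
  P <- matrix(0, 4, 4)
  P[1, 2] <- P[2, 1] <- 0.5
  X <- rmvn(2000, pcor_to_cor(P))
  net <- estimate_ggm(pearson_matrix(X))
  test <- ggm_edge_test(net, alpha = 0.05)
  strong <- test$from == "V1" & test$to == "V2"
  expect_true(test$retained[strong])
  expect_true(all(!ggm_edge_test(net, alpha = 0)$retained))
  holm <- ggm_edge_test(net, alpha = 0.05, adjust = "holm")
  expect_true(all(holm$p >= test$p))
})

test_that("edge-list and GraphML exports round-trip through igraph", {
  set.seed(2)
  C <- rand_pd_cor(5)
  dimnames(C) <- list(letters[1:5], letters[1:5])
  net <- estimate_ggm(C, n = 60)
  el <- as_edge_list(net)
  expect_named(el, c("from", "to", "weight"))
  expect_equal(nrow(el), 10)  # dense 5-node network
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 10)
  ew <- igraph::E(g)$weight
  expect_equal(sum(abs(ew)), global_strength(net), tolerance = 1e-6)
})
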