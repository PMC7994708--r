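test_that("single-symptom panel reduces to the closed-form AR(1) slope", {
  set.seed(81)
  n <- 25
  sc <- array(sample(0:4, n * 3, replace = TRUE), dim = c(n, 3, 1))
  panel <- symptom_panel(sc, sprintf("s%02d", 1:n), symptom_names = "Mood")
  fit <- estimate_panel_gvar(panel)
  # oracle: stack the two transitions, univariate OLS slope
  x <- c(sc[, 1, 1], sc[, 2, 1])
  y <- c(sc[, 2, 1], sc[, 3, 1])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(fit$B[1, 1]), slope, tolerance = 1e-10)
  expect_equal(unname(fit$intercepts[1]), mean(y) - slope * mean(x),
               tolerance = 1e-10)
  expect_equal(fit$n_transitions, 2 * n)
})

test_that("null dynamics are recovered as near-zero coefficients", {
  cfg <- generator_config(n_subjects = 2000, p = 4,
                          B_true = matrix(0, 4, 4),
                          contemporaneous_pcor = matrix(0, 4, 4),
                          between_sd = 0,
                          wave_means = matrix(0, 3, 4), seed = 82)
  panel <- generate_panel(cfg)
  fit <- estimate_panel_gvar(attr(panel, "latent"))
  expect_lt(max(abs(fit$B)), 0.06)
})

test_that("a known sparse temporal matrix is recovered from latent panels", {
  # stationary wave means: the pooled estimator assumes them, and this
  # simulation is meant to match the model assumptions exactly
  B <- default_temporal_B()
  B <- B * (0.6 / max(Mod(eigen(B, only.values = TRUE)$values)))
  cfg <- generator_config(n_subjects = 4000, B_true = B, between_sd = 0,
                          wave_means = matrix(0, 3, 11), seed = 83)
  panel <- generate_panel(cfg)
  fit <- estimate_panel_gvar(attr(panel, "latent"))
  expect_lt(mean(abs(fit$B - B)), 0.03)
  # contemporaneous residual network matches the generator's
  expect_lt(mean(abs(fit$contemporaneous - cfg$contemporaneous_pcor)), 0.03)
})

test_that("stationarity check returns the spectral radius", {
  s <- check_stationarity(0.5 * diag(3))
  expect_equal(s$spectral_radius, 0.5)
  expect_true(s$stationary)
  s1 <- check_stationarity(diag(2))
  expect_equal(s1$spectral_radius, 1)
  expect_false(s1$stationary)
  # p = 2 non-symmetric case against the quadratic-formula eigenvalues
  B <- matrix(c(0.5, 0.2, 0.3, 0.4), 2, 2, byrow = TRUE)
  tr <- sum(diag(B))
  det_ <- B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1]
  roots <- (tr + c(-1, 1) * sqrt(tr^2 - 4 * det_)) / 2
  expect_equal(check_stationarity(B)$spectral_radius, max(abs(roots)),
               tolerance = 1e-12)
  expect_error(check_stationarity(matrix(1, 2, 3)), "square")
})

test_that("Wald edge tests behave at alpha 0, under the null, and with power", {
  # alpha = 0 retains nothing
  set.seed(85)
  panel <- generate_panel(generator_config(seed = 85))
  fit <- estimate_panel_gvar(panel)
  expect_false(any(temporal_edge_test(fit, alpha = 0)$retained))
  # null data: retention rate near alpha across many coefficients
  cfg0 <- generator_config(n_subjects = 400, p = 6,
                           B_true = matrix(0, 6, 6),
                           contemporaneous_pcor = matrix(0, 6, 6),
                           between_sd = 0, wave_means = matrix(0, 3, 6),
                           seed = 86)
  fit0 <- estimate_panel_gvar(attr(generate_panel(cfg0), "latent"))
  rate <- mean(temporal_edge_test(fit0, alpha = 0.05)$retained)
  expect_lt(rate, 0.15)
  # one strong true cross-lag is retained at large n
  B <- matrix(0, 3, 3)
  B[2, 1] <- 0.4  # symptom 1 drives symptom 2
  cfgp <- generator_config(n_subjects = 3000, p = 3, B_true = B,
                           contemporaneous_pcor = matrix(0, 3, 3),
                           between_sd = 0, wave_means = matrix(0, 3, 3),
                           seed = 87)
  fitp <- estimate_panel_gvar(attr(generate_panel(cfgp), "latent"))
  tt <- temporal_edge_test(fitp, alpha = 0.05)
  expect_true(tt$retained[tt$from == "V1" & tt$to == "V2"])
  # holm is never more liberal
  th <- temporal_edge_test(fitp, alpha = 0.05, adjust = "holm")
  expect_lte(sum(th$retained), sum(tt$retained))
})

test_that("standardization makes B invariant to affine rescaling", {
  set.seed(88)
  panel <- generate_panel(generator_config(n_subjects = 300, seed = 88))
  lat <- attr(panel, "latent")
  rescaled <- lat
  scale_f <- seq(0.5, 3, length.out = dim(lat)[3])
  for (k in seq_len(dim(lat)[3])) {
    rescaled[, , k] <- lat[, , k] * scale_f[k] + k
  }
  f1 <- estimate_panel_gvar(lat, standardize = TRUE)
  f2 <- estimate_panel_gvar(rescaled, standardize = TRUE)
  expect_equal(f1$B, f2$B, tolerance = 1e-10)
})

test_that("between-person variance biases pooled B up; centering biases down", {
  B <- 0.3 * diag(3)
  cfg <- generator_config(n_subjects = 3000, p = 3, B_true = B,
                          contemporaneous_pcor = matrix(0, 3, 3),
                          between_sd = 1, wave_means = matrix(0, 3, 3),
                          seed = 89)
  lat <- attr(generate_panel(cfg), "latent")
  none <- estimate_panel_gvar(lat, centering = "none")
  cent <- estimate_panel_gvar(lat, centering = "subject_mean")
  # stable person effects masquerade as autocorrelation when uncentered
  expect_gt(mean(diag(none$B)), 0.3)
  # with T = 3 the within transformation over-corrects (Nickell bias)
  expect_lt(mean(diag(cent$B)), 0.3)
})

test_that("degenerate inputs are rejected", {
  sc <- array(sample(0:4, 10, replace = TRUE), dim = c(10, 1, 1))
  one_wave <- symptom_panel(sc, sprintf("s%d", 1:10), symptom_names = "Mood")
  expect_error(estimate_panel_gvar(one_wave), "2 waves")
  expect_error(estimate_panel_gvar(matrix(0, 3, 3)), "symptom_panel")
  # too few transitions
  small <- toy_panel(n = 4, waves = 2, p = 6, seed = 90)
  expect_error(estimate_panel_gvar(small), "transitions")
})
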