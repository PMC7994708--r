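test_that("generation is reproducible from the config seed", {
  cfg <- generator_config(seed = 101)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$scores, b$scores)
  expect_identical(attr(a, "latent"), attr(b, "latent"))
  c_ <- generate_panel(generator_config(seed = 102))
  expect_false(identical(a$scores, c_$scores))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(generate_panel(cfg)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("generated panels satisfy all panel invariants", {
  panel <- generate_panel(generator_config(seed = 103))
  expect_s3_class(panel, "symptom_panel")
  expect_equal(dim(panel$scores), c(100, 3, 11))
  expect_identical(panel$symptom_names, ymrs_symptoms())
  sc <- as.vector(panel$scores)
  expect_true(all(sc %in% 0:4))
  expect_false(anyDuplicated(panel$subject_ids) > 0)
  # round-trips through the CSV reader (read_panel of a write is identity)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f, "long")
  expect_equal(read_panel(f, "long")$scores, panel$scores)
})

test_that("config invariants are enforced before any sampling", {
  expect_error(generator_config(B_true = diag(1.2, 11)), "spectral radius")
  P_bad <- matrix(0.2, 11, 11)  # nonzero diagonal
  expect_error(generator_config(contemporaneous_pcor = P_bad), "diagonal")
  expect_error(generator_config(thresholds = c(-1, 0, 0, 1)), "increasing")
  expect_error(generator_config(thresholds = c(-1, 0, 1)), "4")
  expect_error(generator_config(wave_means = matrix(0, 2, 11)), "waves x p")
  dense <- matrix(0.5, 11, 11); diag(dense) <- 0
  expect_error(generator_config(contemporaneous_pcor = dense),
               "positive.definite|\\(-1, 1\\)")
})

test_that("latent wave means track the configured declining trajectory", {
  cfg <- generator_config(n_subjects = 400, seed = 104)
  lat <- attr(generate_panel(cfg), "latent")
  for (t in 1:3) {
    m <- colMeans(lat[, t, ])
    se <- apply(lat[, t, ], 2, sd) / sqrt(400)
    expect_true(all(abs(m - cfg$wave_means[t, ]) < 3.5 * se + 1e-8))
  }
  # ordinal severity declines from admission to discharge
  panel <- generate_panel(cfg)
  m0 <- colMeans(panel$scores[, 1, ])
  m2 <- colMeans(panel$scores[, 3, ])
  expect_true(all(m0 >= m2))
  expect_gt(mean(m0) - mean(m2), 1)
})

test_that("the null configuration yields uncorrelated latent columns", {
  cfg <- generator_config(n_subjects = 1500, p = 5,
                          B_true = matrix(0, 5, 5),
                          contemporaneous_pcor = matrix(0, 5, 5),
                          between_sd = 0, wave_means = matrix(0, 3, 5),
                          seed = 105)
  lat <- attr(generate_panel(cfg), "latent")
  flat <- cbind(lat[, 1, ], lat[, 2, ], lat[, 3, ])  # all waves side by side
  C <- cor(flat)
  expect_lt(max(abs(C[upper.tri(C)])), 4 / sqrt(1500))
})

test_that("discretization counts thresholds below the latent value", {
  th <- c(-1.5, -0.5, 0.5, 1.5)
  expect_equal(discretize(c(-9, -1, 0, 1, 9), th), c(0, 1, 2, 3, 4))
  expect_equal(discretize(matrix(c(-9, 9), 1, 2), th),
               matrix(c(0, 4), 1, 2))
  expect_error(discretize(0, c(1, 1, 2, 3)), "increasing")
  # quintile cut-points on a standard normal give a near-uniform score mix
  set.seed(106)
  z <- rnorm(50000)
  q <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  tab <- tabulate(discretize(z, q) + 1, 5) / 50000
  expect_true(all(abs(tab - 0.2) < 0.01))
})

test_that("discretization attenuates cross-sectional correlations", {
  cfg <- generator_config(n_subjects = 1000, seed = 107)
  panel <- generate_panel(cfg)
  lat <- attr(panel, "latent")
  r_lat <- cor(lat[, 1, ])
  r_ord <- cor(panel$scores[, 1, ], method = "spearman")
  m_lat <- mean(abs(r_lat[upper.tri(r_lat)]))
  m_ord <- mean(abs(r_ord[upper.tri(r_ord)]))
  expect_lte(m_ord, m_lat + 0.02)
})

test_that("a single large latent wave recovers the contemporaneous network", {
  P <- default_contemporaneous_pcor()
  cfg <- generator_config(n_subjects = 5000, B_true = matrix(0, 11, 11),
                          contemporaneous_pcor = P, between_sd = 0,
                          wave_means = matrix(0, 3, 11), seed = 108)
  lat <- attr(generate_panel(cfg), "latent")
  net <- estimate_ggm(pearson_matrix(lat[, 2, ]))
  expect_lt(max(abs(net$weights - P)), 0.07)
})

test_that("generator configs serialize to JSON and back", {
  cfg <- generator_config(n_subjects = 17, seed = 109, between_sd = 0.3)
  f <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, f)
  back <- read_generator_config(f)
  expect_equal(back$B_true, cfg$B_true, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$wave_means, cfg$wave_means, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$symptom_names, cfg$symptom_names)
  expect_equal(back$seed, cfg$seed)
  expect_equal(generate_panel(back)$scores, generate_panel(cfg)$scores)
})
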