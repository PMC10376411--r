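test_that("make_true_clpn support, hubs and determinism behave as designed", {
  # full density forces complete off-diagonal support
  B <- make_true_clpn(p = 3, density = 1, seed = 1)
  expect_equal(sum(B[row(B) != col(B)] != 0), 6)
  expect_equal(diag(B), rep(0, 3))

  # a planted OEI hub dominates every other row's absolute sum,
  # and a planted IEI hub every other column's
  B <- make_true_clpn(p = 20, n_hub_out = 1, n_hub_in = 1, density = 0.12,
                      hub_scale = 1.6, seed = 3)
  expect_equal(which.max(rowSums(abs(B))), attr(B, "hub_out"))
  expect_equal(which.max(colSums(abs(B))), attr(B, "hub_in"))

  # seed determinism
  expect_identical(make_true_clpn(p = 20, density = 0.1, seed = 7),
                   make_true_clpn(p = 20, density = 0.1, seed = 7))

  expect_error(make_true_clpn(p = 1, density = 0.5), "p")
  expect_error(make_true_clpn(p = 5, density = 1.5), "density")
  expect_error(make_true_clpn(p = 5, density = 0), "density")
})

test_that("discretize_likert implements the strict-threshold rule", {
  expect_equal(discretize_likert(matrix(-50), c(-0.5, 0.5))[1, 1], 1L)
  expect_equal(discretize_likert(matrix(0), c(-0.5, 0.5))[1, 1], 2L)
  expect_equal(discretize_likert(matrix(50), c(-0.5, 0.5))[1, 1], 3L)
  expect_error(discretize_likert(matrix(0), c(0.5, -0.5)), "increasing")
})

test_that("discretized category frequencies match the normal-CDF gaps", {
  set.seed(11)
  n <- 1e5
  tau <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  x <- matrix(rnorm(n), n, 1)
  d <- discretize_likert(x, tau)
  freq <- tabulate(d, 5) / n
  expected <- diff(c(0, pnorm(tau), 1))
  expect_lt(max(abs(freq - expected)), 0.01)
  # symmetric thresholds give frequencies symmetric about the middle
  counts <- tabulate(d, 5)
  expect_gt(chisq.test(counts[c(1, 5)])$p.value, 0.01)
  expect_gt(chisq.test(counts[c(2, 4)])$p.value, 0.01)
})

test_that("independent-waves config yields near-zero cross-wave correlation", {
  cfg <- generator_config(n_participants = 5000,
                          true_cross_lagged = matrix(0, 20, 20),
                          autoregressive_range = c(0, 0), seed = 21)
  sim <- generate_panel(cfg)
  cc <- cor(sim$panel$wave1_items, sim$panel$wave2_items)
  expect_lt(max(abs(cc)), 4 / sqrt(5000))
})

test_that("a single planted effect is recovered by the OLS oracle", {
  B <- matrix(0, 20, 20)
  B[1, 2] <- 0.5
  cfg <- generator_config(n_participants = 5000, true_cross_lagged = B,
                          autoregressive_range = c(0, 0),
                          covariate_effects = c(age = 0, gender = 0),
                          discretize = FALSE, seed = 33)
  sim <- generate_panel(cfg)
  # oracle: ordinary least squares on the continuous latent data
  fit <- lm(sim$panel$wave2_items[, 2] ~ sim$panel$wave1_items)
  coefs <- coef(fit)[-1]
  expect_gt(coefs[1], 0)
  expect_equal(unname(which.max(abs(coefs))), 1)
  expect_equal(unname(coefs[1]), 0.5, tolerance = 0.1)
})

test_that("generation is byte-identical under a repeated seed", {
  cfg <- generator_config(n_participants = 200, seed = 9)
  s1 <- generate_panel(cfg)
  s2 <- generate_panel(cfg)
  expect_identical(s1$panel$wave1_items, s2$panel$wave1_items)
  expect_identical(s1$panel$wave2_items, s2$panel$wave2_items)
  expect_identical(s1$panel$wave1_screener_total,
                   s2$panel$wave1_screener_total)
  expect_identical(s1$truth$true_autoregressive,
                   s2$truth$true_autoregressive)
})

test_that("non-stationary lag matrices are refused", {
  B <- matrix(0.3, 5, 5); diag(B) <- 0
  cfg <- generator_config(n_participants = 50, n_items = 5,
                          true_cross_lagged = B,
                          autoregressive_range = c(0.9, 0.95), seed = 1)
  expect_error(generate_panel(cfg), "spectral radius")
})

test_that("a too-small sample is flagged as unstable", {
  cfg <- generator_config(n_participants = 10, n_items = 8,
                          true_cross_lagged = matrix(0, 8, 8), seed = 2)
  expect_warning(sim <- generate_panel(cfg), "unstable")
  expect_true(isTRUE(attr(sim$panel, "unstable_estimation")))
})

test_that("screener total tracks the mean symptom score at the set loading", {
  cfg <- generator_config(n_participants = 1e4, seed = 14)
  sim <- generate_panel(cfg)
  r1 <- cor(sim$panel$wave1_screener_total, rowMeans(sim$panel$wave1_items))
  expect_lt(abs(r1 - cfg$screener_loading), 0.05)
})

test_that("panels round-trip through CSV and ground truth through JSON", {
  cfg <- generator_config(n_participants = 50, n_items = 6,
                          true_cross_lagged = matrix(0, 6, 6), seed = 4)
  sim <- generate_panel(cfg)
  dir <- withr::local_tempdir()
  paths <- write_panel(sim, dir)
  raw <- read_panel(paths["wave1"], paths["wave2"], n_items = 6)
  expect_equal(nrow(raw$wave1), 50)
  panel <- match_waves(raw$wave1, raw$wave2)
  expect_identical(unname(panel$wave1_items),
                   unname(sim$panel$wave1_items))
  gt <- jsonlite::read_json(paths["ground_truth"], simplifyVector = TRUE)
  expect_equal(gt$true_autoregressive, sim$truth$true_autoregressive)
})
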