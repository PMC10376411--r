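cent_fn <- function(net) list(oei = out_expected_influence(net),
                              iei = in_expected_influence(net))

test_that("a zero drop proportion reproduces the full sample exactly", {
  pan <- tiny_panel(n = 80, p = 4, seed = 33)
  res <- suppressWarnings(case_dropping_bootstrap(
    pan, estimator = cor_panel_estimator, centrality_fn = cent_fn,
    drop_proportions = c(0, 0.2), n_boot = 10, seed = 1))
  expect_true(all(res$correlations$oei[, 1] == 1))
  expect_true(all(res$correlations$iei[, 1] == 1))
})

test_that("case-dropping is reproducible and stream-disciplined", {
  pan <- tiny_panel(n = 100, p = 4, seed = 34)
  r1 <- case_dropping_bootstrap(pan, estimator = cor_panel_estimator,
                                centrality_fn = cent_fn,
                                drop_proportions = c(0.1, 0.3),
                                n_boot = 8, seed = 2)
  r2 <- case_dropping_bootstrap(pan, estimator = cor_panel_estimator,
                                centrality_fn = cent_fn,
                                drop_proportions = c(0.1, 0.3),
                                n_boot = 8, seed = 2)
  expect_identical(r1$correlations, r2$correlations)
  # raising n_boot leaves the first replicates unchanged
  r3 <- case_dropping_bootstrap(pan, estimator = cor_panel_estimator,
                                centrality_fn = cent_fn,
                                drop_proportions = c(0.1, 0.3),
                                n_boot = 16, seed = 2)
  expect_identical(r3$correlations$oei[1:8, ], r1$correlations$oei)
  expect_error(case_dropping_bootstrap(pan, drop_proportions = c(0.3, 0.1)),
               "increasing")
})

test_that("the CS coefficient implements the quantile rule", {
  grid <- c(0.1, 0.2, 0.3)
  mk <- function(v1, v2, v3)
    list(correlations = list(oei = cbind(v1, v2, v3)),
         drop_proportions = grid)
  # all correlations 1 -> grid maximum
  expect_equal(cs_coefficient(mk(rep(1, 40), rep(1, 40), rep(1, 40)))[["oei"]],
               0.3)
  # all correlations 0 -> 0
  expect_equal(cs_coefficient(mk(rep(0, 40), rep(0, 40), rep(0, 40)))[["oei"]],
               0)
  # passes at 0.1, fails from 0.2 -> 0.1
  pass <- rep(0.95, 40)
  fail <- c(rep(0.2, 10), rep(0.95, 30))  # 5th percentile below 0.7
  expect_equal(cs_coefficient(mk(pass, fail, fail))[["oei"]], 0.1)
  # relaxing the threshold can only raise the coefficient
  res <- mk(pass, fail, fail)
  expect_gte(cs_coefficient(res, threshold = 0.1)[["oei"]],
             cs_coefficient(res, threshold = 0.7)[["oei"]])
})

test_that("median stability decays as more cases are dropped", {
  cfg <- generator_config(n_participants = 800, n_items = 10,
                          true_cross_lagged = make_true_clpn(
                            10, 1, 1, density = 0.2, hub_scale = 1.5,
                            seed = 2),
                          seed = 35)
  pan <- generate_panel(cfg)$panel
  res <- case_dropping_bootstrap(
    pan, estimator = function(p, seed)
      estimate_clpn(p, seed = seed, n_lambda = 30, n_folds = 5),
    centrality_fn = cent_fn,
    drop_proportions = c(0.1, 0.4, 0.7), n_boot = 60, seed = 3)
  med <- apply(res$correlations$oei, 2, median, na.rm = TRUE)
  expect_true(all(diff(med) <= 0.05))  # monotone up to Monte-Carlo noise
  expect_gt(med[1], med[3])
})

test_that("edge bootstrap CIs bracket the sample estimate sensibly", {
  pan <- tiny_panel(n = 90, p = 4, seed = 36)
  eb <- edge_ci_bootstrap(pan, estimator = cor_panel_estimator,
                          n_boot = 40, seed = 4)
  expect_true(all(eb$ci_lower <= eb$ci_upper))
  expect_true(all(eb$ci_lower <= eb$bootstrap_mean + 1e-12))
  # single replicate: degenerate percentiles collapse onto it
  eb1 <- edge_ci_bootstrap(pan, estimator = cor_panel_estimator,
                           n_boot = 1, seed = 5)
  expect_equal(eb1$ci_lower, eb1$ci_upper)
  # reproducibility
  eb2 <- edge_ci_bootstrap(pan, estimator = cor_panel_estimator,
                           n_boot = 40, seed = 4)
  expect_identical(eb$draws, eb2$draws)
})

test_that("null-data bootstrap CIs mostly contain zero", {
  cfg <- generator_config(n_participants = 600, n_items = 8,
                          true_cross_lagged = matrix(0, 8, 8),
                          autoregressive_range = c(0, 0), seed = 37)
  pan <- generate_panel(cfg)$panel
  eb <- edge_ci_bootstrap(pan, estimator = function(p, seed)
    estimate_clpn(p, seed = seed, n_lambda = 30, n_folds = 5),
    n_boot = 60, seed = 6)
  off <- row(eb$sample_weights) != col(eb$sample_weights)
  covers0 <- eb$ci_lower[off] <= 0 & eb$ci_upper[off] >= 0
  expect_gt(mean(covers0), 0.9)
})

test_that("difference tests flag separated pairs and never the diagonal", {
  set.seed(38)
  draws <- cbind(a = rnorm(200, 0, 0.01), b = rnorm(200, 1, 0.01),
                 c = rnorm(200, 0, 0.01))
  dt <- difference_tests(draws)
  expect_false(any(diag(dt$significant)))
  expect_true(dt$significant[1, 2])   # disjoint ranges
  expect_false(dt$significant[1, 3])  # same distribution
  expect_identical(dt$significant[2, 1], dt$significant[1, 2])
  expect_same_numeric(dt$ci_lower[2, 1], -dt$ci_upper[1, 2])
  # an edge compared with itself via identical draws is never significant
  dt2 <- difference_tests(cbind(draws[, 1], draws[, 1]))
  expect_false(dt2$significant[1, 2])
  expect_equal(dt2$ci_lower[1, 2], 0)
})

test_that("stability curves export in long format", {
  pan <- tiny_panel(n = 70, p = 4, seed = 39)
  res <- case_dropping_bootstrap(pan, estimator = cor_panel_estimator,
                                 centrality_fn = cent_fn,
                                 drop_proportions = c(0.1, 0.2),
                                 n_boot = 5, seed = 7)
  long <- stability_long(res)
  expect_equal(nrow(long), 2 * 2 * 5)
  expect_setequal(unique(long$index), c("oei", "iei"))
})
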