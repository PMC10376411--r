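test_that("a 20-item network has 400 estimable directed edges", {
  pan <- generate_panel(generator_config(n_participants = 120, seed = 12))$panel
  net <- estimate_clpn(pan, seed = 1, n_lambda = 40)
  expect_equal(dim(net$weights), c(20L, 20L))
  ed <- edge_density(net)
  expect_equal(ed$n_possible, 400)
  # covariate coefficients live outside the network matrix
  expect_equal(rownames(net$covariate_coefficients), c("age", "gender"))
})

test_that("null panels yield mostly empty cross-lagged networks", {
  # CV-min trades a handful of spurious edges per node for sensitivity;
  # the one-standard-error rule is decisively sparser under the null
  props_min <- numeric(5); props_1se <- numeric(5)
  for (s in 1:5) {
    cfg <- generator_config(n_participants = 2000,
                            true_cross_lagged = matrix(0, 20, 20),
                            autoregressive_range = c(0, 0), seed = 100 + s)
    pan <- generate_panel(cfg)$panel
    off <- upper.tri(diag(20)) | lower.tri(diag(20))
    net <- estimate_clpn(pan, seed = s)
    props_min[s] <- mean(net$weights[off] != 0)
    net1 <- estimate_clpn(pan, seed = s, lambda_rule = "1se")
    props_1se[s] <- mean(net1$weights[off] != 0)
  }
  expect_true(all(props_min <= 0.30))
  expect_lt(mean(props_min), 0.20)
  expect_true(all(props_1se <= 0.10))
})

test_that("estimation is deterministic given the seed", {
  pan <- generate_panel(generator_config(n_participants = 150, n_items = 8,
                                         true_cross_lagged =
                                           matrix(0, 8, 8),
                                         seed = 13))$panel
  n1 <- estimate_clpn(pan, seed = 5, n_lambda = 40)
  n2 <- estimate_clpn(pan, seed = 5, n_lambda = 40)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$lambda_selected, n2$lambda_selected)
})

test_that("covariate adjustment is inert when covariates have no effect", {
  cfg <- generator_config(n_participants = 2000,
                          covariate_effects = c(age = 0, gender = 0),
                          seed = 15)
  pan <- generate_panel(cfg)$panel
  with_cov <- estimate_clpn(pan, include_covariates = TRUE, seed = 2)
  without <- estimate_clpn(pan, include_covariates = FALSE, seed = 2)
  off <- row(with_cov$weights) != col(with_cov$weights)
  d <- abs(with_cov$weights[off] - without$weights[off])
  # agreement is exact for almost every edge; the occasional discrepancy
  # comes from a different cross-validated penalty pick on one node and
  # stays small
  expect_lt(max(d), 0.03)
  expect_gt(mean(d < 0.005), 0.95)
})

test_that("planted cross-lagged structure is recovered", {
  cfg <- generator_config(n_participants = 2000, seed = 16)
  sim <- generate_panel(cfg)
  net <- estimate_clpn(sim$panel, seed = 3)
  off <- row(net$weights) != col(net$weights)
  expect_gt(cor(net$weights[off], sim$truth$true_cross_lagged[off]), 0.7)
  # the planted hubs surface as the top-ranked OEI / IEI nodes
  rr <- rank_report(net, k = 1)
  expect_equal(rr$oei$item, paste0("iat", sim$truth$hub_out))
  expect_equal(rr$iei$item, paste0("iat", sim$truth$hub_in))
})

test_that("network export formats round-trip the weights", {
  pan <- generate_panel(generator_config(n_participants = 100, n_items = 6,
                                         true_cross_lagged =
                                           matrix(0, 6, 6),
                                         seed = 17))$panel
  net <- estimate_clpn(pan, seed = 1, n_lambda = 30)
  dir <- withr::local_tempdir()
  write_network_csv(net, file.path(dir, "m.csv"))
  m <- as.matrix(read.csv(file.path(dir, "m.csv"), row.names = 1))
  expect_equal(unname(m), unname(net$weights), tolerance = 1e-12)
  write_edge_list(net, file.path(dir, "e.csv"), keep_zeros = TRUE)
  e <- read.csv(file.path(dir, "e.csv"))
  expect_equal(nrow(e), 36)
  expect_equal(sum(e$type == "autoregressive"), 6)
})
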