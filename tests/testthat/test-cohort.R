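write_wave_csv <- function(df, dir, name) {
  pth <- file.path(dir, name)
  write.csv(df, pth, row.names = FALSE)
  pth
}

test_that("read_panel validates schema and ranges with row-level reporting", {
  cfg <- generator_config(n_participants = 30, n_items = 20, seed = 5)
  sim <- generate_panel(cfg)
  tabs <- as_wave_tables(sim$panel)
  dir <- withr::local_tempdir()
  p1 <- write_wave_csv(tabs$wave1, dir, "w1.csv")
  p2 <- write_wave_csv(tabs$wave2, dir, "w2.csv")
  raw <- read_panel(p1, p2)
  expect_equal(nrow(raw$wave1), 30)

  bad <- tabs$wave1
  bad$iat3[7] <- 7
  pb <- write_wave_csv(bad, dir, "bad.csv")
  expect_error(read_panel(pb, p2), "iat3 rows 7")

  noc <- tabs$wave1[, setdiff(names(tabs$wave1), "iat5")]
  pn <- write_wave_csv(noc, dir, "noc.csv")
  expect_error(read_panel(pn, p2), "missing column.*iat5")

  pe <- file.path(dir, "empty.csv")
  writeLines("", pe)
  expect_error(read_panel(pe, p2), "schema")
})

test_that("match_waves inner-joins on the key and counts the dropped", {
  mk <- function(ids) {
    data.frame(id = ids, age = 12, gender = 0,
               matrix(3L, length(ids), 3,
                      dimnames = list(NULL, paste0("iat", 1:3))),
               matrix(1L, length(ids), 2,
                      dimnames = list(NULL, paste0("phq", 1:2))))
  }
  pan <- match_waves(mk(1:3), mk(2:4))
  expect_equal(n_participants(pan), 2)
  expect_equal(pan$ids, c(2, 3))
  expect_equal(attr(pan, "dropped_wave1"), 1)
  expect_equal(attr(pan, "dropped_wave2"), 1)

  expect_warning(empty <- match_waves(mk(1:3), mk(4:6)), "no shared keys")
  expect_equal(n_participants(empty), 0)

  dup <- mk(c(1, 1, 2))
  expect_error(match_waves(dup, mk(1:3)), "duplicate keys")
})

test_that("a planted partial overlap is matched exactly", {
  cfg <- generator_config(n_participants = 100, n_items = 10,
                          true_cross_lagged = matrix(0, 10, 10), seed = 8)
  cohort <- simulate_cohort(n_wave1 = 10104, n_wave2 = 8390,
                            n_matched = 2415, config = cfg)
  pan <- match_waves(cohort$wave1, cohort$wave2)
  expect_equal(n_participants(pan), 2415)
  expect_equal(attr(pan, "dropped_wave1"), 10104 - 2415)
  expect_equal(attr(pan, "dropped_wave2"), 8390 - 2415)
})

test_that("screening prevalence and subsetting follow the cutoff rule", {
  pan <- tiny_panel(n = 200, seed = 1)
  scr <- screen_panel(pan, cutoff = 0)
  expect_equal(n_participants(scr$panel), 200)
  expect_equal(scr$prevalence_w1, 100)

  scr8 <- screen_panel(pan, cutoff = 8)
  expect_equal(n_participants(scr8$panel), sum(pan$wave1_screener_total >= 8))
  expect_equal(scr8$prevalence_w1,
               round(100 * mean(pan$wave1_screener_total >= 8), 2))
  expect_error(screen_panel(pan, cutoff = 28), "cutoff")

  # subset size non-increasing in the cutoff; invariant to row order
  sizes <- vapply(0:27, function(ct)
    n_participants(screen_panel(pan, ct)$panel), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  perm <- pan[sample(200)]
  expect_equal(screen_panel(perm, 8)$prevalence_w1, scr8$prevalence_w1)
})

test_that("descriptives reproduce the paired-design identities", {
  pan <- tiny_panel(n = 80, seed = 2)
  tab <- descriptives_table(pan)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$df, rep(79L, 5))
  # dz * sqrt(n) is the t statistic (algebraic identity)
  expect_same_numeric(tab$cohens_dz * sqrt(80), tab$t_statistic, 1e-10)
  expect_true(all(tab$diff_ci_lower <= tab$mean_difference + 1e-12))
  expect_true(all(tab$mean_difference <= tab$diff_ci_upper + 1e-12))
  # invariant to row permutation
  tab2 <- descriptives_table(pan[sample(80)])
  expect_equal(tab2$t_statistic, tab$t_statistic, tolerance = 1e-12)

  # identical waves: zero difference, undefined t
  pan0 <- symptom_panel(1:10, rep(12, 10), rep(0, 10),
                        pan$wave1_items[1:10, ], pan$wave1_items[1:10, ],
                        wave1_screener_total = rep(0, 10),
                        wave2_screener_total = rep(0, 10))
  tab0 <- descriptives_table(pan0)
  expect_equal(tab0$mean_difference, rep(0, 5))
  expect_true(all(tab0$t_undefined))
  expect_true(all(is.na(tab0$t_statistic)))
})

test_that("cronbach_alpha matches its closed form", {
  set.seed(3)
  x <- rnorm(500)
  dup <- cbind(x, x, x)
  expect_equal(cronbach_alpha(dup), 1, tolerance = 1e-12)

  # two independent items: alpha is 0 in expectation
  z <- matrix(rnorm(2e5), ncol = 2)
  expect_lt(abs(cronbach_alpha(z)), 0.05)

  # exchangeable covariance: alpha has a closed form from the generating
  # covariance: total variance k + k(k-1)rho, item variances k
  k <- 5; rho <- 0.3; n <- 1e4
  sigma <- matrix(rho, k, k); diag(sigma) <- 1
  y <- matrix(rnorm(n * k), n, k) %*% chol(sigma)
  alpha_true <- k / (k - 1) * (1 - k / (k + k * (k - 1) * rho))
  expect_lt(abs(cronbach_alpha(y) - alpha_true), 0.01)

  expect_error(cronbach_alpha(matrix(1, 10, 3)), "variance")
  expect_error(cronbach_alpha(matrix(rnorm(10), 10, 1)), "2 items")
})
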