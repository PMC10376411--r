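# Shared fixtures: small panels and cheap estimators used across tests.

# Small ordinal panel built directly (no generator), n participants,
# p items, deterministic from seed.
tiny_panel <- function(n = 60, p = 5, seed = 42) {
  set.seed(seed)
  w1 <- matrix(sample(1:5, n * p, replace = TRUE), n, p,
               dimnames = list(NULL, paste0("iat", 1:p)))
  w2 <- matrix(sample(1:5, n * p, replace = TRUE), n, p,
               dimnames = list(NULL, paste0("iat", 1:p)))
  symptom_panel(ids = seq_len(n), age = sample(10:18, n, TRUE),
                gender = rbinom(n, 1, 0.5),
                wave1_items = w1, wave2_items = w2,
                wave1_screener_total = sample(0:27, n, TRUE),
                wave2_screener_total = sample(0:27, n, TRUE))
}

# Fast symmetric estimator for NCT / resampling logic tests: marginal
# correlations with the diagonal zeroed (a legitimate, deterministic
# network estimator).
cor_estimator <- function(x) {
  r <- cor(x)
  diag(r) <- 0
  r
}

# Panel-level wrapper of the same, for the resampling drivers.
cor_panel_estimator <- function(panel, seed) cor_estimator(panel$wave1_items)

expect_same_numeric <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
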