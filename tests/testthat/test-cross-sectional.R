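test_that("correlation_matrix validates input and matches hand computation", {
  set.seed(21)
  x <- matrix(rnorm(30), 10, 3)
  x[, 2] <- x[, 1]
  expect_equal(correlation_matrix(x)[1, 2], 1)

  # hand-computed Pearson r on a 3 x 3 input (sum formula oracle)
  h <- matrix(c(1, 2, 4, 2, 1, 3, 5, 7, 6), 3, 3)
  R <- correlation_matrix(h)
  hand_r <- function(a, b) {
    n <- length(a)
    (n * sum(a * b) - sum(a) * sum(b)) /
      sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  }
  expect_equal(R[1, 2], hand_r(h[, 1], h[, 2]), tolerance = 1e-12)
  expect_equal(R[1, 3], hand_r(h[, 1], h[, 3]), tolerance = 1e-12)

  xc <- cbind(x[, 1], 5)
  colnames(xc) <- c("a", "b")
  expect_error(correlation_matrix(xc), "constant item.*b")

  set.seed(22)
  big <- matrix(rnorm(3e5), ncol = 3)
  expect_lt(max(abs(correlation_matrix(big)[upper.tri(diag(3))])), 0.02)
})

test_that("ebic_glasso returns an empty network when there is no dependence", {
  net <- ebic_glasso(diag(8), n = 500)
  expect_true(all(net$partial_correlations == 0))
  # heavy shrinkage (large gamma prefers the sparsest model) empties it too
  set.seed(23)
  x <- matrix(rnorm(2000), 500, 4)
  net2 <- ebic_glasso(cor(x), n = 500, gamma = 10)
  expect_true(all(net2$partial_correlations == 0))
})

test_that("a chain graph loses its endpoint edge in partial correlation", {
  set.seed(24)
  n <- 2000
  x <- rnorm(n)
  y <- 0.7 * x + rnorm(n, sd = sqrt(1 - 0.49))
  z <- 0.7 * y + rnorm(n, sd = sqrt(1 - 0.49))
  net <- estimate_cs_network(cbind(x = x, y = y, z = z))
  pc <- net$partial_correlations
  expect_true(pc["x", "y"] != 0)
  expect_true(pc["y", "z"] != 0)
  expect_lt(abs(pc["x", "z"]), 0.05)
})

test_that("partial correlations are symmetric, bounded and equivariant", {
  set.seed(25)
  for (s in 1:5) {
    x <- matrix(rnorm(300 * 6), 300, 6) %*%
      chol(0.4 + 0.6 * diag(6))
    R <- cor(x)
    net <- ebic_glasso(R, n = 300)
    pc <- net$partial_correlations
    expect_lt(max(abs(pc - t(pc))), 1e-10)
    expect_true(all(abs(pc) <= 1))
    expect_equal(diag(pc), rep(0, 6))
    prm <- sample(6)
    net_p <- ebic_glasso(R[prm, prm], n = 300)
    expect_equal(net_p$partial_correlations,
                 pc[prm, prm], tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("selected edge counts do not shrink with more data", {
  cfg_net <- function(n, s) {
    set.seed(s)
    sig <- matrix(0.35, 8, 8); diag(sig) <- 1
    x <- matrix(rnorm(n * 8), n, 8) %*% chol(sig)
    net <- estimate_cs_network(x)
    sum(net$partial_correlations[upper.tri(diag(8))] != 0)
  }
  for (s in 1:10) expect_lte(cfg_net(200, s), cfg_net(2000, s))
})

test_that("non-PSD inputs error unless repair is requested", {
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.9; R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9
  expect_error(ebic_glasso(R, n = 100), "positive semi-definite")
  net <- ebic_glasso(R, n = 100, repair_psd = TRUE)
  expect_true(is.matrix(net$partial_correlations))
})

test_that("global strength is the absolute upper-triangle sum", {
  expect_equal(global_strength(matrix(0, 5, 5)), 0)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- -0.3
  expect_equal(global_strength(m), 0.5)
})

test_that("network_correlation matches a hand-vectorized oracle", {
  set.seed(26)
  a <- matrix(rnorm(400), 20, 20)
  expect_equal(network_correlation(a, a), 1)
  expect_equal(network_correlation(a, -a), -1)
  b <- matrix(rnorm(400), 20, 20)
  # oracle: explicit off-diagonal vectorization (directed case)
  va <- as.numeric(a)[as.logical(row(a) != col(a))]
  vb <- as.numeric(b)[as.logical(row(b) != col(b))]
  expect_equal(network_correlation(a, b), cor(va, vb), tolerance = 1e-12)
  expect_lt(abs(network_correlation(a, b)), 0.2)
  # symmetric case uses the upper triangle
  sa <- a + t(a); sb <- b + t(b)
  expect_equal(network_correlation(sa, sb),
               cor(sa[upper.tri(sa)], sb[upper.tri(sb)]), tolerance = 1e-12)
  expect_error(network_correlation(a, matrix(0, 3, 3)), "dimensions")
  expect_error(network_correlation(diag(3) * 0, diag(3) * 0),
               "zero-variance")
})
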