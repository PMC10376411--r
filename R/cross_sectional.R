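# Undirected per-wave networks: regularized partial correlations from a
# graphical lasso over a penalty path, with the extended BIC selecting the
# penalty. These networks feed the permutation comparison test and the
# matrix-correlation sensitivity analysis.

#' Item correlation matrix
#'
#' @param items numeric matrix (n x p), n >= 3, no constant column.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(items, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  items <- as.matrix(items)
  if (nrow(items) < 3) stopf("need n >= 3")
  csd <- apply(items, 2, sd)
  if (any(csd == 0)) {
    labs <- colnames(items)
    if (is.null(labs)) labs <- paste0("item", seq_len(ncol(items)))
    stopf("constant item(s): %s", paste(labs[csd == 0], collapse = ", "))
  }
  cor(items, method = method)
}

#' EBIC-selected graphical lasso network
#'
#' Estimates sparse precision matrices along a descending log-spaced
#' penalty grid with an off-diagonal graphical lasso, scores each with the
#' extended Bayesian information criterion
#' \deqn{EBIC = -2 loglik + E log(n) + 4 gamma E log(p)}
#' (E = nonzero upper-triangle edges), picks the minimizer, and converts
#' the selected precision Theta to partial correlations
#' \code{rho_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)}.
#'
#' @param R correlation matrix (positive semi-definite within tolerance).
#' @param n number of observations behind \code{R}.
#' @param gamma EBIC hyperparameter (>= 0); 0.5 by default.
#' @param n_lambda,lambda_min_ratio penalty-grid shape.
#' @param repair_psd clip tiny negative eigenvalues to restore positive
#'   semi-definiteness instead of erroring.
#' @return Object of class \code{cs_network}: \code{partial_correlations}
#'   (symmetric, zero diagonal), \code{lambda}, \code{ebic_gamma},
#'   \code{n_used}, plus the scored grid (\code{lambda_grid}, \code{ebic}).
#' @export
ebic_glasso <- function(R, n, gamma = 0.5, n_lambda = 100L,
                        lambda_min_ratio = 0.01, repair_psd = FALSE) {
  if (!is_symmetric_matrix(R, tol = 1e-8)) stopf("R must be symmetric")
  if (gamma < 0) stopf("`gamma` must be >= 0")
  p <- nrow(R)
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    if (!repair_psd)
      stopf(paste("R is not positive semi-definite (min eigenvalue %.2e);",
                  "rerun with repair_psd = TRUE to clip"), min(ev))
    ed <- eigen(R, symmetric = TRUE)
    R <- ed$vectors %*% diag(pmax(ed$values, 1e-8)) %*% t(ed$vectors)
    R <- stats::cov2cor((R + t(R)) / 2)
  }
  lmax <- max(abs(R[upper.tri(R)]))
  if (lmax <= 0) lmax <- 1e-3
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  thetas <- glasso_path(R, grid)
  ebic <- numeric(n_lambda)
  for (l in seq_len(n_lambda)) {
    th <- thetas[, , l]
    ld <- determinant(th, logarithm = TRUE)
    ll <- (n / 2) * (as.numeric(ld$modulus) - sum(R * th))
    E <- sum(th[upper.tri(th)] != 0)
    ebic[l] <- -2 * ll + E * log(n) + 4 * gamma * E * log(p)
  }
  sel <- which.min(ebic)
  th <- thetas[, , sel]
  d <- sqrt(diag(th))
  pc <- -th / tcrossprod(d)
  diag(pc) <- 0
  pc <- pmin(pmax((pc + t(pc)) / 2, -1), 1)
  dimnames(pc) <- dimnames(R)
  structure(list(partial_correlations = pc, lambda = grid[sel],
                 ebic_gamma = gamma, n_used = as.integer(n),
                 lambda_grid = grid, ebic = ebic),
            class = "cs_network")
}

#' Estimate a cross-sectional symptom network from raw item scores
#'
#' Convenience wrapper: \code{\link{correlation_matrix}} then
#' \code{\link{ebic_glasso}}.
#'
#' @inheritParams correlation_matrix
#' @inheritParams ebic_glasso
#' @export
estimate_cs_network <- function(items, method = c("pearson", "spearman"),
                                gamma = 0.5, n_lambda = 100L,
                                lambda_min_ratio = 0.01,
                                repair_psd = FALSE) {
  R <- correlation_matrix(items, method)
  ebic_glasso(R, n = nrow(as.matrix(items)), gamma = gamma,
              n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
              repair_psd = repair_psd)
}

#' @export
print.cs_network <- function(x, ...) {
  p <- nrow(x$partial_correlations)
  E <- sum(x$partial_correlations[upper.tri(x$partial_correlations)] != 0)
  cat(sprintf(paste0("Regularized partial-correlation network: %d nodes, ",
                     "%d of %d edges nonzero\n"), p, E, p * (p - 1) / 2))
  cat(sprintf("  lambda = %.4f (EBIC, gamma = %.2f), n = %d\n",
              x$lambda, x$ebic_gamma, x$n_used))
  invisible(x)
}

#' Global strength of an undirected network
#'
#' Sum of absolute upper-triangle edge weights.
#'
#' @param net a \code{cs_network} or symmetric weight matrix.
#' @return Scalar global strength.
#' @export
global_strength <- function(net) {
  w <- if (inherits(net, "cs_network")) net$partial_correlations
  else as.matrix(net)
  sum(abs(w[upper.tri(w)]))
}

#' Correlation between two networks' edge weights
#'
#' Pearson correlation between the vectorized unique edge weights: the
#' upper triangle when both matrices are symmetric (within tolerance), all
#' off-diagonal entries otherwise (directed networks).
#'
#' @param A,B networks (\code{clpn}, \code{cs_network}) or weight matrices
#'   of equal dimension.
#' @return Scalar Pearson correlation.
#' @export
network_correlation <- function(A, B) {
  gw <- function(x) {
    if (inherits(x, "cs_network")) x$partial_correlations
    else if (inherits(x, "clpn")) x$weights
    else as.matrix(x)
  }
  a <- gw(A); b <- gw(B)
  if (!all(dim(a) == dim(b))) stopf("networks have different dimensions")
  if (is_symmetric_matrix(a, 1e-10) && is_symmetric_matrix(b, 1e-10)) {
    va <- upper_tri_values(a); vb <- upper_tri_values(b)
  } else {
    va <- off_diag_values(a); vb <- off_diag_values(b)
  }
  if (sd(va) == 0 || sd(vb) == 0)
    stopf("zero-variance edge vector: correlation undefined")
  cor(va, vb)
}
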