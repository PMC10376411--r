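# Node-level lasso machinery: penalty path by cyclic coordinate descent
# (compiled Gram-form solver) and seeded K-fold cross-validation for the
# penalty choice. Inputs are expected column-standardized (predictors) and
# centered (outcome); estimate_clpn() prepares data accordingly.

# Log-spaced descending penalty grid from lambda_max (smallest penalty that
# zeroes every coefficient) down to lambda_min_ratio * lambda_max.
lambda_grid <- function(X, y, n_lambda = 100L, lambda_min_ratio = 1e-4) {
  lmax <- max(abs(crossprod(X, y)) / nrow(X))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Lasso coefficient path
#'
#' Solves, for each penalty on the grid, \deqn{min_b (1/2n) ||y - Xb||^2 +
#' lambda ||b||_1} by cyclic coordinate descent with warm starts along the
#' (descending) grid; convergence when the largest coefficient change in a
#' sweep falls below \code{tol}. Constant predictor columns keep a zero
#' coefficient, with a warning.
#'
#' @param X predictor matrix, column-standardized (mean 0, sd 1).
#' @param y outcome vector, centered.
#' @param lambda optional penalty grid (descending); derived from the data
#'   when \code{NULL}.
#' @param n_lambda,lambda_min_ratio grid size and lower endpoint ratio used
#'   when \code{lambda} is \code{NULL}.
#' @param tol,maxit coordinate-descent convergence tolerance and sweep cap per penalty (a safety limit; typical fits converge in far fewer sweeps).
#' @return List of class \code{lasso_path}: \code{lambda} and \code{beta}
#'   (q x length(lambda) coefficient matrix).
#' @export
lasso_path <- function(X, y, lambda = NULL, n_lambda = 100L,
                       lambda_min_ratio = 1e-4, tol = 1e-7,
                       maxit = 2000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stopf("non-finite values in the lasso inputs")
  if (nrow(X) != length(y)) stopf("nrow(X) != length(y)")
  if (nrow(X) <= 2) stopf("need n > 2")
  csd <- apply(X, 2, sd)
  if (any(csd == 0))
    warnf("constant predictor column(s) %s: coefficients fixed at 0",
          paste(which(csd == 0), collapse = ", "))
  if (is.null(lambda)) lambda <- lambda_grid(X, y, n_lambda, lambda_min_ratio)
  n <- nrow(X)
  G <- crossprod(X) / n
  b <- drop(crossprod(X, y)) / n
  beta <- cd_lasso_path(G, b, as.numeric(lambda), tol = tol,
                        maxit = as.integer(maxit))
  rownames(beta) <- colnames(X)
  structure(list(lambda = as.numeric(lambda), beta = beta),
            class = "lasso_path")
}

# CV work-horse over precomputed fold pieces; shared by select_lambda_cv and
# estimate_clpn (which reuses fold Gram matrices across the p node fits).
.cv_lasso <- function(folds, y, lambda, tol, maxit) {
  L <- length(lambda)
  errs <- matrix(NA_real_, length(folds), L)
  for (f in seq_along(folds)) {
    fd <- folds[[f]]
    bt <- drop(crossprod(fd$X_train, y[fd$train])) / fd$n_train
    beta <- cd_lasso_path(fd$G_train, bt, lambda, tol = tol, maxit = maxit)
    pred <- fd$X_test %*% beta
    errs[f, ] <- colMeans((y[fd$test] - pred)^2)
  }
  list(mean = colMeans(errs),
       se = apply(errs, 2, sd) / sqrt(nrow(errs)))
}

.make_folds <- function(X, foldid) {
  lapply(sort(unique(foldid)), function(f) {
    tr <- which(foldid != f); te <- which(foldid == f)
    Xtr <- X[tr, , drop = FALSE]
    list(train = tr, test = te, n_train = length(tr),
         X_train = Xtr, G_train = crossprod(Xtr) / length(tr),
         X_test = X[te, , drop = FALSE])
  })
}

#' Select the lasso penalty by seeded K-fold cross-validation
#'
#' Fold assignment is drawn from \code{seed} (or supplied via
#' \code{foldid}); the penalty minimizing mean held-out squared error is
#' selected (\code{rule = "min"}), or the largest penalty within one
#' standard error of that minimum (\code{rule = "1se"}); the model is then
#' refit on the full data at the selected penalty.
#'
#' @inheritParams lasso_path
#' @param n_folds number of folds, between 2 and n.
#' @param seed integer seed for the fold assignment.
#' @param foldid optional explicit fold assignment (overrides \code{seed}).
#' @param rule penalty rule, \code{"min"} (default) or \code{"1se"}.
#' @return List of class \code{lasso_cv}: \code{coefficients},
#'   \code{lambda} (selected), \code{lambda_grid}, \code{cv_mean},
#'   \code{cv_se}, \code{foldid}.
#' @export
select_lambda_cv <- function(X, y, n_folds = 10L, lambda = NULL,
                             n_lambda = 100L, lambda_min_ratio = 1e-4,
                             seed = 1L, foldid = NULL,
                             rule = c("min", "1se"),
                             tol = 1e-7, maxit = 2000L) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_folds < 2 || n_folds > n)
    stopf("`n_folds` must lie in [2, n = %d]", n)
  if (is.null(lambda)) lambda <- lambda_grid(X, y, n_lambda, lambda_min_ratio)
  if (is.null(foldid))
    foldid <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  cv <- .cv_lasso(.make_folds(X, foldid), y, lambda, tol, maxit)
  sel <- .pick_lambda(lambda, cv$mean, cv$se, rule)
  full <- lasso_path(X, y, lambda = lambda, tol = tol, maxit = maxit)
  structure(list(coefficients = full$beta[, sel$index],
                 intercept = 0,
                 lambda = sel$lambda, lambda_index = sel$index,
                 lambda_grid = lambda, cv_mean = cv$mean, cv_se = cv$se,
                 rule = rule, foldid = foldid),
            class = "lasso_cv")
}

.pick_lambda <- function(lambda, cv_mean, cv_se, rule) {
  i_min <- which.min(cv_mean)
  if (rule == "1se") {
    thr <- cv_mean[i_min] + cv_se[i_min]
    # grid is descending: the largest qualifying penalty is the earliest
    i_sel <- which(cv_mean <= thr)[1]
  } else i_sel <- i_min
  list(index = i_sel, lambda = lambda[i_sel])
}
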