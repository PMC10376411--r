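# Directed cross-lagged panel network estimation: one penalized regression
# per wave-2 item on all wave-1 items (plus covariates), with the penalty
# chosen by seeded cross-validation. Edge [i, j] is the coefficient of
# wave-1 item i predicting wave-2 item j; the diagonal carries the
# autoregressive coefficients. Covariate coefficients are estimated but
# kept outside the network matrix, so centralities and comparisons never
# mix symptom and covariate edges.

#' Estimate a cross-lagged panel network
#'
#' For each wave-2 item, z-scores all wave-1 items (and, if requested, age
#' and gender) as predictors and the outcome, and fits a lasso regression
#' with the penalty selected by K-fold cross-validation
#' (\code{\link{select_lambda_cv}}). One fold assignment, drawn from
#' \code{seed}, is shared by all node fits, so each column of the network
#' is invariant to the order in which the nodes are fit. Coefficients are
#' on the standardized scale, making edge weights comparable across nodes.
#'
#' @param panel a \code{\link{symptom_panel}}.
#' @param include_covariates adjust for age and gender per node.
#' @param n_folds folds for the penalty cross-validation.
#' @param seed integer seed for the fold assignment.
#' @param n_lambda,lambda_min_ratio penalty-grid shape per node.
#' @param lambda_rule \code{"min"} (default) or \code{"1se"}.
#' @return Object of class \code{clpn}: \code{weights} (p x p, rows =
#'   wave-1 source, columns = wave-2 target, diagonal = autoregressive),
#'   \code{item_labels}, \code{lambda_selected}, \code{covariate_coefficients}
#'   (covariates x p, or NULL), and \code{meta}.
#' @export
estimate_clpn <- function(panel, include_covariates = TRUE, n_folds = 10L,
                          seed = 1L, n_lambda = 100L,
                          lambda_min_ratio = 1e-4,
                          lambda_rule = c("min", "1se")) {
  stopifnot(inherits(panel, "symptom_panel"))
  lambda_rule <- match.arg(lambda_rule)
  n <- n_participants(panel)
  p <- ncol(panel$wave1_items)
  if (n < 30) warnf("n = %d is small; network estimates will be noisy", n)
  labels <- colnames(panel$wave1_items)
  if (is.null(labels)) labels <- paste0("item", seq_len(p))
  if (length(labels) != p) stopf("item label count != p")

  Xraw <- panel$wave1_items
  covs <- NULL
  if (include_covariates) {
    covs <- cbind(age = panel$age, gender = panel$gender)
  }
  Xall <- cbind(Xraw, covs)
  # z-score predictors; constant columns (e.g. single-gender subsample)
  # become all-zero and keep zero coefficients
  mu <- colMeans(Xall)
  sdv <- apply(Xall, 2, sd)
  const <- sdv == 0
  if (any(const))
    warnf("constant predictor(s) %s fixed at coefficient 0",
          paste(colnames(Xall)[const], collapse = ", "))
  sdv[const] <- 1
  X <- sweep(sweep(Xall, 2, mu), 2, sdv, "/")
  X[, const] <- 0
  q <- ncol(X)

  foldid <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  folds <- .make_folds(X, foldid)
  G <- crossprod(X) / n

  weights <- matrix(0, p, p, dimnames = list(labels, labels))
  covcoef <- if (include_covariates)
    matrix(0, ncol(covs), p, dimnames = list(colnames(covs), labels)) else NULL
  lambda_sel <- numeric(p)

  # under-determined samples get a higher penalty floor (the usual
  # convention): the unpenalized end of the path is not identified there
  if (n < q) lambda_min_ratio <- max(lambda_min_ratio, 0.01)

  for (j in seq_len(p)) {
    yj <- panel$wave2_items[, j]
    sy <- sd(yj)
    if (sy == 0) {
      warnf("wave-2 item %s is constant; its incoming edges are 0", labels[j])
      next
    }
    y <- (yj - mean(yj)) / sy
    lambda <- lambda_grid(X, y, n_lambda, lambda_min_ratio)
    cv <- .cv_lasso(folds, y, lambda, tol = 1e-6, maxit = 200L)
    sel <- .pick_lambda(lambda, cv$mean, cv$se, lambda_rule)
    b <- drop(crossprod(X, y)) / n
    beta <- cd_lasso_path(G, b, lambda[seq_len(sel$index)],
                          tol = 1e-7, maxit = 2000L)[, sel$index]
    weights[, j] <- beta[seq_len(p)]
    if (include_covariates) covcoef[, j] <- beta[(p + 1):q]
    lambda_sel[j] <- sel$lambda
  }

  structure(list(weights = weights, item_labels = labels,
                 lambda_selected = lambda_sel,
                 covariate_coefficients = covcoef,
                 meta = list(n = n, n_folds = n_folds, seed = seed,
                             standardized = TRUE,
                             lambda_rule = lambda_rule,
                             include_covariates = include_covariates)),
            class = "clpn")
}

#' @export
print.clpn <- function(x, ...) {
  p <- nrow(x$weights)
  off <- x$weights[row(x$weights) != col(x$weights)]
  cat(sprintf("Cross-lagged panel network: %d nodes, n = %d\n",
              p, x$meta$n))
  cat(sprintf("  %d of %d cross-lagged edges nonzero (%.1f%%)\n",
              sum(off != 0), length(off), 100 * mean(off != 0)))
  cat(sprintf("  autoregressive coefficients: %.2f to %.2f\n",
              min(diag(x$weights)), max(diag(x$weights))))
  invisible(x)
}

# Accept either a clpn object or a bare weight matrix.
.clpn_weights <- function(net) {
  if (inherits(net, "clpn")) net$weights
  else if (is.matrix(net) && nrow(net) == ncol(net)) net
  else stopf("expected a clpn object or square weight matrix")
}

#' Count of estimable directed edges and realized density
#'
#' A p-node cross-lagged network has p^2 estimable directed edges
#' (p autoregressive plus p*(p-1) cross-lagged).
#'
#' @param net a \code{clpn} or square weight matrix.
#' @return List with \code{n_possible}, \code{n_nonzero}, and
#'   \code{density_pct} (percent of possible edges that are nonzero).
#' @export
edge_density <- function(net) {
  w <- .clpn_weights(net)
  list(n_possible = length(w), n_nonzero = sum(w != 0),
       density_pct = 100 * sum(w != 0) / length(w))
}

#' Write a network as a dense labeled CSV matrix
#' @param net \code{clpn}, \code{cs_network}, or matrix.
#' @param path output path.
#' @export
write_network_csv <- function(net, path) {
  w <- if (inherits(net, "cs_network")) net$partial_correlations
  else .clpn_weights(net)
  write.csv(as.data.frame(w), path, row.names = TRUE)
  invisible(path)
}

#' Write a network as an edge-list CSV
#'
#' Columns: source, target, weight, type. For a directed cross-lagged
#' network the type is \code{autoregressive} (diagonal) or
#' \code{cross_lagged}; for a symmetric partial-correlation network each
#' upper-triangle edge appears once with type \code{partial_correlation}.
#'
#' @param net \code{clpn}, \code{cs_network}, or matrix.
#' @param path output path.
#' @param keep_zeros include zero-weight entries.
#' @export
write_edge_list <- function(net, path, keep_zeros = FALSE) {
  if (inherits(net, "cs_network")) {
    w <- net$partial_correlations
    idx <- which(upper.tri(w), arr.ind = TRUE)
    df <- data.frame(source = rownames(w)[idx[, 1]],
                     target = colnames(w)[idx[, 2]],
                     weight = w[idx], type = "partial_correlation")
  } else {
    w <- .clpn_weights(net)
    labs <- rownames(w)
    if (is.null(labs)) labs <- paste0("item", seq_len(nrow(w)))
    idx <- which(matrix(TRUE, nrow(w), ncol(w)), arr.ind = TRUE)
    df <- data.frame(source = labs[idx[, 1]], target = labs[idx[, 2]],
                     weight = w[idx],
                     type = ifelse(idx[, 1] == idx[, 2],
                                   "autoregressive", "cross_lagged"))
  }
  if (!keep_zeros) df <- df[df$weight != 0, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
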