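# Permutation network comparison test for two conditions measured on the
# same participants (two waves). Global strength invariance (S), structure
# invariance (M = largest absolute edge difference) and per-edge invariance
# are tested against a permutation null built by randomly swapping each
# participant's two condition vectors (paired design) or by relabeling
# pooled rows (unpaired).

#' Permutation network comparison test
#'
#' Estimates one undirected network per condition, computes the observed
#' global-strength difference \code{S = |strength_a - strength_b|}, the
#' structure statistic \code{M = max_ij |edge_a - edge_b|} and all per-edge
#' absolute differences, then builds their permutation null: in the paired
#' design each participant's condition-a and condition-b item vectors are
#' independently swapped with probability 1/2; in the unpaired design the
#' pooled rows are randomly relabeled. P-values use the add-one estimator
#' \code{(1 + #(null >= observed)) / (1 + n_permutations)}, so they are
#' never exactly zero.
#'
#' @param items_a,items_b n x p item matrices for the two conditions
#'   (paired rows: row r is the same participant in both).
#' @param estimator function mapping an item matrix to a symmetric weight
#'   matrix (or a \code{cs_network}); default
#'   \code{\link{estimate_cs_network}}. If an estimation fails inside a
#'   permutation, that permutation is retried with a fresh swap pattern and
#'   the retry is counted.
#' @param n_permutations at least 20.
#' @param seed integer seed; the full permutation stream is reproducible.
#' @param paired use the within-participant swap null (default) or the
#'   group-relabeling null.
#' @param ... passed to the default estimator.
#' @return Object of class \code{clpn_nct} with the observed strengths,
#'   \code{s_diff}, \code{p_global}, \code{m_statistic}, \code{p_structure},
#'   the symmetric \code{edge_p_values} matrix, the observed networks and
#'   bookkeeping (\code{n_permutations}, \code{seed}, \code{n_retries}).
#' @export
nct_paired <- function(items_a, items_b, estimator = NULL,
                       n_permutations = 1000L, seed = 1L, paired = TRUE,
                       ...) {
  items_a <- as.matrix(items_a); items_b <- as.matrix(items_b)
  if (!all(dim(items_a) == dim(items_b)))
    stopf("conditions must share n and p")
  if (n_permutations < 20)
    stopf("n_permutations < 20 gives too coarse a p-value resolution")
  if (is.null(estimator))
    estimator <- function(x) estimate_cs_network(x, ...)
  est <- function(x) {
    net <- estimator(x)
    if (inherits(net, "cs_network")) net$partial_correlations else net
  }
  n <- nrow(items_a); p <- ncol(items_a)

  net_a <- est(items_a); net_b <- est(items_b)
  s_a <- global_strength(net_a); s_b <- global_strength(net_b)
  s_obs <- abs(s_a - s_b)
  diff_obs <- abs(net_a - net_b)
  m_obs <- max(diff_obs[upper.tri(diff_obs)])

  null_s <- numeric(n_permutations)
  null_m <- numeric(n_permutations)
  edge_count <- matrix(0, p, p)
  n_retries <- 0L
  for (b in seq_len(n_permutations)) {
    attempt <- 0L
    repeat {
      res <- with_seed(child_seed(seed, b, attempt), {
        if (paired) {
          swap <- runif(n) < 0.5
          pa <- items_a; pb <- items_b
          pa[swap, ] <- items_b[swap, , drop = FALSE]
          pb[swap, ] <- items_a[swap, , drop = FALSE]
        } else {
          pool <- rbind(items_a, items_b)
          pick <- sample(2 * n, n)
          pa <- pool[pick, , drop = FALSE]
          pb <- pool[-pick, , drop = FALSE]
        }
        tryCatch({
          na_ <- est(pa); nb_ <- est(pb)
          list(ok = TRUE,
               s = abs(global_strength(na_) - global_strength(nb_)),
               d = abs(na_ - nb_))
        }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
      })
      if (res$ok) break
      attempt <- attempt + 1L
      n_retries <- n_retries + 1L
      if (attempt > 25L)
        stopf("estimator kept failing inside permutation %d: %s", b, res$msg)
    }
    null_s[b] <- res$s
    null_m[b] <- max(res$d[upper.tri(res$d)])
    edge_count <- edge_count + (res$d >= diff_obs)
  }
  edge_p <- (1 + edge_count) / (1 + n_permutations)
  diag(edge_p) <- 1
  dimnames(edge_p) <- dimnames(net_a)
  structure(list(global_strength_a = s_a, global_strength_b = s_b,
                 s_diff = s_obs,
                 p_global = (1 + sum(null_s >= s_obs)) / (1 + n_permutations),
                 m_statistic = m_obs,
                 p_structure = (1 + sum(null_m >= m_obs)) / (1 + n_permutations),
                 edge_p_values = edge_p,
                 edge_difference = diff_obs,
                 network_a = net_a, network_b = net_b,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), paired = paired,
                 n_retries = n_retries),
            class = "clpn_nct")
}

#' @export
print.clpn_nct <- function(x, ...) {
  cat("Permutation network comparison test",
      if (x$paired) "(paired)\n" else "(unpaired)\n")
  cat(sprintf("  global strength: %.2f vs %.2f, S = %.2f, p = %.3f\n",
              x$global_strength_a, x$global_strength_b, x$s_diff,
              x$p_global))
  cat(sprintf("  structure: M = %.2f, p = %.3f  (%d permutations)\n",
              x$m_statistic, x$p_structure, x$n_permutations))
  invisible(x)
}

#' Edges with significant invariance violations
#'
#' Lists edges whose permutation p-value falls below \code{alpha}, sorted
#' by p. Per-edge p-values are unadjusted unless \code{holm = TRUE}, in
#' which case Holm-adjusted p-values are used for the cut and reported.
#'
#' @param res a \code{clpn_nct}.
#' @param alpha significance level.
#' @param holm apply Holm multiplicity adjustment across the
#'   \code{p*(p-1)/2} edges.
#' @return Data frame with edge indices, labels, condition weights, the
#'   absolute difference and (adjusted) p-values.
#' @export
edge_invariance_report <- function(res, alpha = 0.05, holm = FALSE) {
  stopifnot(inherits(res, "clpn_nct"))
  p <- nrow(res$edge_p_values)
  idx <- which(upper.tri(res$edge_p_values), arr.ind = TRUE)
  labs <- rownames(res$edge_p_values)
  if (is.null(labs)) labs <- paste0("item", seq_len(p))
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   edge = paste(labs[idx[, 1]], labs[idx[, 2]], sep = "--"),
                   weight_a = res$network_a[idx],
                   weight_b = res$network_b[idx],
                   abs_difference = res$edge_difference[idx],
                   p_value = res$edge_p_values[idx])
  df$p_adjusted <- if (holm) stats::p.adjust(df$p_value, "holm") else
    df$p_value
  df <- df[order(df$p_adjusted, df$p_value), ]
  out <- df[df$p_adjusted < alpha, ]
  attr(out, "adjustment") <- if (holm) "holm" else "none"
  rownames(out) <- NULL
  out
}
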