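# Stability and accuracy machinery: case-dropping bootstrap with the
# correlation-stability (CS) coefficient, nonparametric bootstrap edge
# confidence intervals, and CI-based difference tests. All resampling is
# reproducible from one master seed; replicate b of any stream uses a
# deterministic child seed, so raising n_boot leaves earlier replicates
# unchanged.

# Default estimator / centrality plumbing shared by the bootstrap drivers.
.default_estimator <- function(panel, seed) estimate_clpn(panel, seed = seed)
.default_centrality <- function(net) {
  list(oei = out_expected_influence(net), iei = in_expected_influence(net))
}

#' Case-dropping bootstrap for centrality stability
#'
#' For each drop proportion q and bootstrap iteration, retains a random
#' subsample of \code{ceiling((1 - q) * n)} rows without replacement,
#' re-estimates the network, recomputes each centrality index, and stores
#' its Pearson correlation with the full-sample centrality. A drop
#' proportion of exactly 0 is allowed as a degenerate check: the full panel
#' (and the full-fit seed) is reused, so those correlations are exactly 1.
#'
#' @param panel a \code{\link{symptom_panel}}.
#' @param estimator function \code{(panel, seed) -> clpn or weight matrix};
#'   default \code{\link{estimate_clpn}}.
#' @param centrality_fn function mapping a network to a named list of
#'   centrality vectors; default OEI and IEI.
#' @param drop_proportions increasing values in [0, 1).
#' @param n_boot iterations per proportion.
#' @param seed master seed.
#' @return Object of class \code{clpn_stability}: \code{correlations} (a
#'   named list, one n_boot x length(drop_proportions) matrix per index),
#'   \code{drop_proportions}, \code{n_boot}, \code{seed},
#'   \code{n_failed} (estimator failures, recorded as NA).
#' @export
case_dropping_bootstrap <- function(panel, estimator = .default_estimator,
                                    centrality_fn = .default_centrality,
                                    drop_proportions = seq(0.05, 0.75, 0.05),
                                    n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(panel, "symptom_panel"))
  if (any(diff(drop_proportions) <= 0) || any(drop_proportions < 0) ||
      any(drop_proportions >= 1))
    stopf("`drop_proportions` must be increasing values in [0, 1)")
  n <- n_participants(panel)
  p <- ncol(panel$wave1_items)
  if (ceiling((1 - max(drop_proportions)) * n) < 3 * p)
    warnf("smallest retained subsample < 3p = %d rows; stability estimates
may be unreliable", 3 * p)
  full_seed <- child_seed(seed, 0L, 0L)
  full <- centrality_fn(estimator(panel, full_seed))
  idxn <- names(full)
  cors <- lapply(full, function(x)
    matrix(NA_real_, n_boot, length(drop_proportions)))
  n_failed <- 0L
  for (qi in seq_along(drop_proportions)) {
    q <- drop_proportions[qi]
    keep <- ceiling((1 - q) * n)
    for (b in seq_len(n_boot)) {
      cseed <- child_seed(seed, qi, b)
      if (q == 0) {
        sub <- panel
        cseed <- full_seed  # identical sample, identical estimation
      } else {
        sub <- panel[with_seed(cseed, sample(n, keep))]
      }
      cent <- tryCatch(centrality_fn(estimator(sub, cseed)),
                       error = function(e) NULL)
      if (is.null(cent)) { n_failed <- n_failed + 1L; next }
      for (nm in idxn) {
        cors[[nm]][b, qi] <-
          if (identical(cent[[nm]], full[[nm]])) 1
          else if (sd(cent[[nm]]) == 0 || sd(full[[nm]]) == 0) NA_real_
          else cor(full[[nm]], cent[[nm]])
      }
    }
  }
  structure(list(correlations = cors, drop_proportions = drop_proportions,
                 full_centrality = full, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), n_failed = n_failed),
            class = "clpn_stability")
}

#' Correlation-stability coefficient
#'
#' The largest drop proportion in the grid at which the empirical
#' \code{(1 - probability)} quantile of the bootstrap correlations still
#' reaches \code{threshold} — i.e. the maximum share of cases that can be
#' dropped while the re-estimated centrality correlates at least
#' \code{threshold} with the original with probability \code{probability}.
#' Returns 0 when no grid point qualifies. By convention, CS >= 0.25 is
#' considered acceptable and CS >= 0.5 stable.
#'
#' @param res a \code{clpn_stability} (or a list with elements
#'   \code{correlations} and \code{drop_proportions} of the same shape).
#' @param threshold correlation threshold (default 0.7).
#' @param probability required probability (default 0.95).
#' @return Named numeric vector, one CS coefficient per centrality index.
#' @export
cs_coefficient <- function(res, threshold = 0.7, probability = 0.95) {
  if (is.null(res$correlations) || is.null(res$drop_proportions))
    stopf("`res` must carry `correlations` and `drop_proportions`")
  vapply(res$correlations, function(m) {
    ok <- vapply(seq_along(res$drop_proportions), function(qi) {
      v <- m[, qi]
      v <- v[!is.na(v)]
      if (!length(v)) return(FALSE)
      quantile(v, 1 - probability, names = FALSE, type = 7) >= threshold
    }, logical(1))
    if (any(ok)) max(res$drop_proportions[ok]) else 0
  }, numeric(1))
}

#' @export
print.clpn_stability <- function(x, ...) {
  cs <- cs_coefficient(x)
  cat(sprintf("Case-dropping bootstrap: %d iterations x %d proportions\n",
              x$n_boot, length(x$drop_proportions)))
  for (nm in names(cs))
    cat(sprintf("  CS-coefficient (%s): %.2f\n", nm, cs[nm]))
  if (x$n_failed > 0) cat(sprintf("  %d failed iterations\n", x$n_failed))
  invisible(x)
}

#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' Resamples participants with replacement, re-estimates the network, and
#' forms percentile confidence intervals for every edge from the bootstrap
#' distribution.
#'
#' @inheritParams case_dropping_bootstrap
#' @param conf confidence level (default 0.95).
#' @return Object of class \code{clpn_edge_boot}: \code{sample_weights}
#'   (full-sample network), \code{ci_lower}, \code{ci_upper},
#'   \code{bootstrap_mean} (matrices), \code{draws} (n_boot x p^2, edges in
#'   column-major order, retained for difference tests), \code{n_boot},
#'   \code{seed}, \code{n_failed}.
#' @export
edge_ci_bootstrap <- function(panel, estimator = .default_estimator,
                              n_boot = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(inherits(panel, "symptom_panel"))
  n <- n_participants(panel)
  p <- ncol(panel$wave1_items)
  if (n < 3 * p) warnf("n = %d < 3p: bootstrap CIs will be wide", n)
  full <- estimator(panel, child_seed(seed, 0L, 0L))
  w_full <- .clpn_weights(full)
  draws <- matrix(NA_real_, n_boot, length(w_full))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    cseed <- child_seed(seed, 1L, b)
    sub <- panel[with_seed(cseed, sample(n, n, replace = TRUE))]
    w <- tryCatch(.clpn_weights(estimator(sub, cseed)),
                  error = function(e) NULL)
    if (is.null(w)) { n_failed <- n_failed + 1L; next }
    draws[b, ] <- as.numeric(w)
  }
  a <- (1 - conf) / 2
  qs <- apply(draws, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE,
              names = FALSE)
  shape <- function(v) matrix(v, nrow(w_full), ncol(w_full),
                              dimnames = dimnames(w_full))
  structure(list(sample_weights = w_full,
                 ci_lower = shape(qs[1, ]), ci_upper = shape(qs[2, ]),
                 bootstrap_mean = shape(colMeans(draws, na.rm = TRUE)),
                 draws = draws, conf = conf,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 n_failed = n_failed),
            class = "clpn_edge_boot")
}

#' @export
print.clpn_edge_boot <- function(x, ...) {
  wd <- x$ci_upper - x$ci_lower
  cat(sprintf("Bootstrap edge CIs: %d iterations, %.0f%% level\n",
              x$n_boot, 100 * x$conf))
  cat(sprintf("  median CI width %.3f (max %.3f)\n",
              stats::median(wd), max(wd)))
  if (x$n_failed > 0) cat(sprintf("  %d failed iterations\n", x$n_failed))
  invisible(x)
}

#' Bootstrap difference tests between edges or centrality values
#'
#' For each pair of quantities, forms the percentile bootstrap CI of the
#' difference of their values and flags the pair significant when that CI
#' excludes zero. Accepts a \code{\link{edge_ci_bootstrap}} result (pairs =
#' edges) or any n_boot x m matrix of bootstrap draws (e.g. centrality
#' vectors per replicate).
#'
#' @param boot a \code{clpn_edge_boot} or a numeric matrix of draws.
#' @param conf confidence level.
#' @return List with logical \code{significant} (m x m, all-FALSE
#'   diagonal and symmetric) and matrices \code{ci_lower}, \code{ci_upper}
#'   of the pairwise difference CIs (row minus column).
#' @export
difference_tests <- function(boot, conf = 0.95) {
  draws <- if (inherits(boot, "clpn_edge_boot")) boot$draws else
    as.matrix(boot)
  m <- ncol(draws)
  a <- (1 - conf) / 2
  lo <- matrix(0, m, m); hi <- matrix(0, m, m)
  sig <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) {
    di <- draws[, i]
    for (j in (i + 1):m) {
      d <- di - draws[, j]
      q <- quantile(d, c(a, 1 - a), na.rm = TRUE, names = FALSE)
      lo[i, j] <- q[1]; hi[i, j] <- q[2]
      lo[j, i] <- -q[2]; hi[j, i] <- -q[1]
      s <- q[1] > 0 || q[2] < 0
      sig[i, j] <- s; sig[j, i] <- s
    }
  }
  list(significant = sig, ci_lower = lo, ci_upper = hi)
}

#' Long-format export of stability curves
#'
#' One row per (index, proportion, iteration), suitable for plotting the
#' familiar stability curves.
#'
#' @param res a \code{clpn_stability}.
#' @param path optional CSV path; when given the frame is also written.
#' @export
stability_long <- function(res, path = NULL) {
  out <- do.call(rbind, lapply(names(res$correlations), function(nm) {
    m <- res$correlations[[nm]]
    data.frame(index = nm,
               drop_proportion = rep(res$drop_proportions,
                                     each = nrow(m)),
               iteration = rep(seq_len(nrow(m)),
                               times = ncol(m)),
               correlation = as.numeric(m))
  }))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
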