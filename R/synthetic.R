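# Synthetic two-wave Likert panel generator with known cross-lagged ground
# truth. Latent wave-1 vectors are multivariate normal (exchangeable
# baseline plus local dependence); wave-2 latents follow a lag-1 linear
# model
#   X2 = X1 %*% (B + diag(a)) + covariates %*% gamma + noise,
# and both waves are discretized to ordinal categories by fixed thresholds.
# A correlated depression-style screener with a cutoff subgroup is attached
# so that cohort screening is exercised end to end.

# Fixed generator constants (see the methods vignette for the calibration
# rationale; these are design constants, not user dials):
#  - .screener_communality: shared-variance proportion of each screener item;
#  - .screener_attenuation: one-off estimate of how much ordinal
#    discretization attenuates the latent screener/symptom correlation; the
#    latent loading is inflated by 1/.screener_attenuation so the *observed*
#    total-score correlation lands on screener_loading;
#  - .screener_cum_probs: cumulative category probabilities of a screener
#    item at zero latent shift (thresholds via qnorm), calibrated so that
#    the default cohort shows roughly 14% above the cutoff of 8 at wave 1;
#  - default wave-2 screener shift reproduces the modest rise in prevalence
#    across the online-learning period (to roughly 18%).
.screener_communality <- 0.75
.screener_attenuation <- 0.80
.screener_cum_probs <- c(0.76, 0.93, 0.982)

#' Construct a sparse true cross-lagged weight matrix
#'
#' Builds a reproducible sparse off-diagonal matrix of cross-lagged effects
#' with optional planted "hub" nodes: hub-out rows (nodes that predict many
#' others, i.e. high out-expected-influence) and hub-in columns (nodes
#' predicted by many others, high in-expected-influence). Hub-out nodes are
#' the first \code{n_hub_out} items and hub-in nodes the last
#' \code{n_hub_in} items, so they never coincide for reasonable counts.
#' By construction each hub-out row has the maximum absolute row sum and
#' each hub-in column the maximum absolute column sum.
#'
#' @param p number of items (nodes); at least 2.
#' @param n_hub_out,n_hub_in number of planted high-OEI / high-IEI nodes.
#' @param density fraction of the p*(p-1) off-diagonal cells that are
#'   nonzero, in (0, 1].
#' @param hub_scale multiplicative inflation of hub row/column weights
#'   (positive).
#' @param seed integer seed; the sparsity pattern and weights are fully
#'   reproducible from it.
#' @param weight_range absolute-size range of the base nonzero weights.
#' @param prob_positive probability that a nonzero weight is positive.
#' @return A p x p numeric matrix with zero diagonal and attributes
#'   \code{hub_out} and \code{hub_in} (integer node indices).
#' @export
make_true_clpn <- function(p, n_hub_out = 0L, n_hub_in = 0L, density,
                           hub_scale = 1, seed = 1L,
                           weight_range = c(0.05, 0.25),
                           prob_positive = 0.85) {
  if (!is_count(p) || p < 2) stopf("`p` must be an integer >= 2, got %s", p)
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1)
    stopf("`density` must lie in (0, 1], got %s", density)
  if (!is_count(n_hub_out) || !is_count(n_hub_in))
    stopf("hub counts must be non-negative integers")
  if (hub_scale <= 0) stopf("`hub_scale` must be positive")
  n_cells <- p * (p - 1)
  m <- max(1L, round(density * n_cells))
  if (density * n_cells < n_hub_out + n_hub_in)
    stopf("density * p * (p-1) = %.1f cannot accommodate %d hub nodes",
          density * n_cells, n_hub_out + n_hub_in)
  if (n_hub_out + n_hub_in > p)
    stopf("more hub nodes than items")

  hub_out <- if (n_hub_out > 0) seq_len(n_hub_out) else integer(0)
  hub_in <- if (n_hub_in > 0) p - seq_len(n_hub_in) + 1L else integer(0)

  with_seed(seed, {
    B <- matrix(0, p, p)
    off <- which(row(B) != col(B))
    # hubs predict / are predicted by many nodes: their support spans at
    # least 30% of the possible partners (and never less than the average
    # row share), which is what makes a hub a hub and keeps its influence
    # sum estimable
    per_node <- max(1L, round(density * (p - 1)))
    per_hub <- max(per_node, min(p - 1L, ceiling(0.3 * (p - 1))))
    forced <- integer(0)
    for (i in hub_out) {
      cols <- sample(setdiff(seq_len(p), i), per_hub)
      forced <- c(forced, (cols - 1L) * p + i)
    }
    for (j in hub_in) {
      rows <- sample(setdiff(seq_len(p), j), per_hub)
      forced <- c(forced, (j - 1L) * p + rows)
    }
    forced <- unique(forced)
    remaining <- setdiff(off, forced)
    n_extra <- max(0L, m - length(forced))
    support <- c(forced, sample(remaining, min(n_extra, length(remaining))))
    w <- runif(length(support), weight_range[1], weight_range[2]) *
      ifelse(runif(length(support)) < prob_positive, 1, -1)
    B[support] <- w
    # hub edges are positive (a hub must dominate the *signed* influence
    # sums, which are what OEI/IEI measure), then inflated
    if (length(hub_out))
      B[hub_out, ] <- abs(B[hub_out, , drop = FALSE]) * hub_scale
    if (length(hub_in))
      B[, hub_in] <- abs(B[, hub_in, drop = FALSE]) * hub_scale
    # enforce dominance of every hub row/column over the largest absolute
    # (hence also signed) sum among the other nodes, with a 40% margin so
    # the ranking survives estimation noise and shrinkage
    for (pass in 1:2) {
      if (length(hub_out)) {
        others <- setdiff(seq_len(p), hub_out)
        top <- max(rowSums(abs(B[others, , drop = FALSE])))
        for (i in hub_out) {
          s <- sum(B[i, ])
          if (s < 1.4 * top) B[i, ] <- B[i, ] * (1.4 * top / s)
        }
      }
      if (length(hub_in)) {
        others <- setdiff(seq_len(p), hub_in)
        top <- max(colSums(abs(B[, others, drop = FALSE])))
        for (j in hub_in) {
          s <- sum(B[, j])
          if (s < 1.4 * top) B[, j] <- B[, j] * (1.4 * top / s)
        }
      }
    }
    diag(B) <- 0
    attr(B, "hub_out") <- hub_out
    attr(B, "hub_in") <- hub_in
    B
  })
}

#' Generator configuration for synthetic two-wave panels
#'
#' Collects every parameter of the generating model. Defaults emulate a
#' two-wave adolescent questionnaire cohort: 20 five-level items whose
#' latent correlation (exchangeable baseline plus a decaying local
#' component, average ~0.43) gives an internal consistency near 0.93 with
#' heterogeneous partial correlations, a sparse cross-lagged matrix with
#' one planted high-OEI and one high-IEI node, moderate autoregression,
#' and a 9-item 0-3 screener whose total correlates with the mean symptom
#' score at \code{screener_loading}.
#'
#' @param n_participants number of matched participants.
#' @param n_items number of symptom items (default 20).
#' @param n_screener_items number of screener items (default 9, scored
#'   0 to \code{screener_levels - 1}).
#' @param true_cross_lagged p x p matrix of true cross-lagged effects
#'   (zero diagonal); default plants one OEI hub and one IEI hub via
#'   \code{\link{make_true_clpn}}.
#' @param autoregressive_range range from which per-item autoregressive
#'   coefficients are drawn uniformly.
#' @param latent_wave1_correlation baseline (exchangeable) off-diagonal
#'   correlation of the wave-1 latents, in [0, 1).
#' @param latent_local_correlation,latent_local_decay strength and
#'   geometric decay of an additional local dependence component: items i
#'   and j share \code{latent_local_correlation *
#'   latent_local_decay^(|i-j|-1)} extra correlation. This gives the
#'   wave-1 latents heterogeneous partial correlations (a questionnaire's
#'   item-cluster texture); with only the exchangeable part every true
#'   partial correlation is identical and small, which degenerates the
#'   cross-sectional network analyses. Set to 0 for a purely exchangeable
#'   structure.
#' @param noise_sd standard deviation of the wave-2 innovation noise.
#' @param correlated_innovations if \code{TRUE} (default) the wave-2
#'   innovations share the wave-1 latent correlation structure (stable
#'   trait and common-method variance persists across waves, keeping
#'   wave-2 internal consistency realistic); if \code{FALSE} innovations
#'   are item-independent. Either way innovations are independent of the
#'   wave-1 latents, so cross-lagged coefficients are unaffected.
#' @param likert_levels number of ordinal categories (>= 2).
#' @param screener_levels number of screener categories (default 4: 0-3).
#' @param screener_loading target correlation between the observed screener
#'   total and the observed mean symptom score, per wave.
#' @param covariate_effects named vector of additive wave-2 latent effects
#'   for the covariates \code{age} (applied to z-scored age) and
#'   \code{gender} (0/1 coded).
#' @param screener_shift length-2 latent mean shift of the screener at the
#'   two waves; the default raises wave-2 prevalence above wave 1.
#' @param discretize if \code{FALSE} the panel keeps the continuous latent
#'   scores (used for estimator property checks on the latent scale).
#' @param seed integer master seed; one stream governs all draws.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n_participants,
                             n_items = 20L,
                             n_screener_items = 9L,
                             true_cross_lagged = NULL,
                             autoregressive_range = c(0.2, 0.45),
                             latent_wave1_correlation = 0.38,
                             latent_local_correlation = 0.25,
                             latent_local_decay = 0.5,
                             noise_sd = 0.8,
                             correlated_innovations = TRUE,
                             likert_levels = 5L,
                             screener_levels = 4L,
                             screener_loading = 0.6,
                             covariate_effects = c(age = 0.1, gender = 0.1),
                             screener_shift = c(0, 0.14),
                             discretize = TRUE,
                             seed = 1L) {
  if (!is_count(n_participants) || n_participants < 1)
    stopf("`n_participants` must be a positive integer")
  if (!is_count(n_items) || n_items < 2) stopf("`n_items` must be >= 2")
  if (likert_levels < 2) stopf("`likert_levels` must be >= 2")
  if (noise_sd <= 0) stopf("`noise_sd` must be positive")
  if (latent_wave1_correlation < 0 || latent_wave1_correlation >= 1)
    stopf("`latent_wave1_correlation` must lie in [0, 1)")
  if (latent_local_correlation < 0 ||
      latent_wave1_correlation + latent_local_correlation >= 1)
    stopf("latent correlation components must stay below 1")
  if (is.null(true_cross_lagged))
    true_cross_lagged <- make_true_clpn(n_items, n_hub_out = 1L,
                                        n_hub_in = 1L, density = 0.12,
                                        hub_scale = 1.6,
                                        seed = child_seed(seed, 1L))
  if (!is.matrix(true_cross_lagged) ||
      nrow(true_cross_lagged) != n_items ||
      ncol(true_cross_lagged) != n_items)
    stopf("`true_cross_lagged` must be a %d x %d matrix", n_items, n_items)
  cfg <- list(n_participants = as.integer(n_participants),
              n_items = as.integer(n_items),
              n_screener_items = as.integer(n_screener_items),
              true_cross_lagged = true_cross_lagged,
              autoregressive_range = autoregressive_range,
              latent_wave1_correlation = latent_wave1_correlation,
              latent_local_correlation = latent_local_correlation,
              latent_local_decay = latent_local_decay,
              noise_sd = noise_sd,
              correlated_innovations = isTRUE(correlated_innovations),
              likert_levels = as.integer(likert_levels),
              screener_levels = as.integer(screener_levels),
              screener_loading = screener_loading,
              covariate_effects = covariate_effects,
              screener_shift = screener_shift,
              discretize = isTRUE(discretize),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Discretize latent scores to ordinal categories
#'
#' Maps each latent value to \code{1 + (number of thresholds strictly below
#' it)}, so thresholds \code{(-0.5, 0.5)} send a latent 0 to category 2.
#'
#' @param latent numeric matrix (n x p) of latent scores.
#' @param thresholds numeric vector of strictly increasing thresholds shared
#'   by all items, or a list of one such vector per item.
#' @return Integer matrix of the same shape with values in
#'   \code{1:(length(thresholds) + 1)}.
#' @export
discretize_likert <- function(latent, thresholds) {
  if (!is.matrix(latent)) latent <- as.matrix(latent)
  p <- ncol(latent)
  th <- if (is.list(thresholds)) thresholds else rep(list(thresholds), p)
  if (length(th) != p) stopf("need one threshold vector per item")
  out <- matrix(0L, nrow(latent), p, dimnames = dimnames(latent))
  for (j in seq_len(p)) {
    tj <- th[[j]]
    if (any(diff(tj) <= 0))
      stopf("thresholds for item %d are not strictly increasing", j)
    out[, j] <- 1L + as.integer(rowSums(outer(latent[, j], tj, ">")))
  }
  out
}

# Screener block for one wave: latent score tied to the mean symptom latent,
# split over items, discretized to 0..(levels-1); returns items and totals.
.make_screener <- function(symptom_latent_mean, loading, n_items, levels,
                           shift) {
  n <- length(symptom_latent_mean)
  lam <- min(0.99, loading / .screener_attenuation)
  m_std <- as.numeric(scale(symptom_latent_mean))
  s_lat <- lam * m_std + sqrt(1 - lam^2) * rnorm(n) + shift
  h <- .screener_communality
  tau <- qnorm(.screener_cum_probs)
  if (levels != length(tau) + 1L) {
    # generic fallback: equal-probability categories
    tau <- qnorm(seq_len(levels - 1L) / levels)
  }
  items <- matrix(0L, n, n_items)
  for (i in seq_len(n_items)) {
    u <- sqrt(h) * s_lat + sqrt(1 - h) * rnorm(n)
    items[, i] <- as.integer(rowSums(outer(u, tau, ">")))
  }
  colnames(items) <- paste0("phq", seq_len(n_items))
  list(items = items, total = as.integer(rowSums(items)))
}

#' Generate a matched two-wave symptom panel with known ground truth
#'
#' Draws wave-1 latents from a zero-mean multivariate normal with
#' exchangeable correlation, forms wave-2 latents through the true
#' cross-lagged matrix plus autoregression, covariate effects and Gaussian
#' noise, discretizes both waves by fixed equal-probability thresholds, and
#' attaches age, gender and a correlated screener. Refuses lag matrices
#' whose spectral radius reaches 1 (the implied first-order vector
#' autoregression would be non-stationary).
#'
#' @param config a \code{\link{generator_config}}.
#' @return A list of class \code{clpn_sim} with components \code{panel}
#'   (a \code{\link{symptom_panel}}) and \code{truth} (class
#'   \code{clpn_ground_truth}: true cross-lagged matrix, true autoregressive
#'   vector, per-item thresholds, seed).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$n_items
  n <- config$n_participants
  with_seed(config$seed, {
    draw <- .draw_wave_pair(config)
    truth <- structure(
      list(true_cross_lagged = config$true_cross_lagged,
           true_autoregressive = draw$a,
           discretization_thresholds = draw$thresholds,
           hub_out = attr(config$true_cross_lagged, "hub_out"),
           hub_in = attr(config$true_cross_lagged, "hub_in"),
           seed = config$seed),
      class = "clpn_ground_truth")
    panel <- symptom_panel(
      ids = seq_len(n), age = draw$age, gender = draw$gender,
      wave1_items = draw$w1, wave2_items = draw$w2,
      wave1_screener = draw$scr1$items, wave2_screener = draw$scr2$items,
      ordinal = config$discretize,
      likert_levels = config$likert_levels,
      screener_levels = config$screener_levels)
    if (n < p + 5) {
      attr(panel, "unstable_estimation") <- TRUE
      warnf("n = %d is below p + 5 = %d; network estimation will be unstable",
            n, p + 5)
    }
    structure(list(panel = panel, truth = truth), class = "clpn_sim")
  })
}

# Wave-1 latent correlation matrix: exchangeable baseline plus a
# geometrically decaying local component (unit diagonal, PSD-checked).
.wave1_sigma <- function(config) {
  p <- config$n_items
  d <- abs(outer(seq_len(p), seq_len(p), "-"))
  sigma <- config$latent_wave1_correlation +
    config$latent_local_correlation * config$latent_local_decay^(d - 1)
  diag(sigma) <- 1
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stopf("wave-1 latent correlation matrix is not positive definite")
  sigma
}

# Core draw shared by generate_panel and simulate_cohort; assumes the RNG
# state is already seeded by the caller.
.draw_wave_pair <- function(config, n = config$n_participants) {
  p <- config$n_items
  a <- runif(p, config$autoregressive_range[1], config$autoregressive_range[2])
  lag <- config$true_cross_lagged + diag(a, p)
  sr <- max(abs(eigen(lag, only.values = TRUE)$values))
  if (sr >= 1)
    stopf("combined lag matrix has spectral radius %.3f >= 1 (non-stationary)",
          sr)
  sigma <- .wave1_sigma(config)
  x1 <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  age <- sample(10:18, n, replace = TRUE)
  gender <- rbinom(n, 1L, 0.5)
  gam <- config$covariate_effects
  age_z <- as.numeric(scale(age))
  eps <- matrix(rnorm(n * p), n, p)
  if (config$correlated_innovations) eps <- eps %*% chol(sigma)
  x2 <- x1 %*% lag +
    outer(age_z * unname(gam["age"]), rep(1, p)) +
    outer(gender * unname(gam["gender"]), rep(1, p)) +
    config$noise_sd * eps
  k <- config$likert_levels
  tau <- qnorm(seq_len(k - 1L) / k)
  thresholds <- rep(list(tau), p)
  if (config$discretize) {
    w1 <- discretize_likert(x1, thresholds)
    w2 <- discretize_likert(x2, thresholds)
  } else {
    w1 <- x1; w2 <- x2
  }
  colnames(w1) <- colnames(w2) <- paste0("iat", seq_len(p))
  scr1 <- .make_screener(rowMeans(x1), config$screener_loading,
                         config$n_screener_items, config$screener_levels,
                         config$screener_shift[1])
  scr2 <- .make_screener(rowMeans(x2), config$screener_loading,
                         config$n_screener_items, config$screener_levels,
                         config$screener_shift[2])
  list(w1 = w1, w2 = w2, age = age, gender = gender, a = a,
       thresholds = thresholds, scr1 = scr1, scr2 = scr2)
}

#' Simulate a two-wave cohort with partial overlap
#'
#' Emulates a field cohort where each wave reaches a different set of
#' respondents and only a subset can be matched across waves: generates
#' \code{n_matched} participants observed at both waves plus wave-specific
#' extras, and returns the two raw wave tables (with the shared schema
#' \code{id, age, gender, iat*, phq*}) ready for \code{\link{match_waves}}.
#'
#' @param n_wave1,n_wave2 total rows in each wave table.
#' @param n_matched number of participants present in both.
#' @param config a \code{\link{generator_config}} (its
#'   \code{n_participants} is ignored in favour of the counts here).
#' @return List with \code{wave1}, \code{wave2} (data frames) and
#'   \code{truth}.
#' @export
simulate_cohort <- function(n_wave1, n_wave2, n_matched, config) {
  stopifnot(n_matched <= n_wave1, n_matched <= n_wave2, n_matched >= 1)
  with_seed(config$seed, {
    matched <- .draw_wave_pair(config, n = n_matched)
    extra1 <- n_wave1 - n_matched
    extra2 <- n_wave2 - n_matched
    e1 <- if (extra1 > 0) .draw_wave_pair(config, n = extra1) else NULL
    e2 <- if (extra2 > 0) .draw_wave_pair(config, n = extra2) else NULL
    truth <- structure(
      list(true_cross_lagged = config$true_cross_lagged,
           true_autoregressive = matched$a,
           discretization_thresholds = matched$thresholds,
           hub_out = attr(config$true_cross_lagged, "hub_out"),
           hub_in = attr(config$true_cross_lagged, "hub_in"),
           seed = config$seed),
      class = "clpn_ground_truth")
    w1 <- data.frame(id = seq_len(n_matched), age = matched$age,
                     gender = matched$gender, matched$w1, matched$scr1$items)
    w2 <- data.frame(id = seq_len(n_matched), age = matched$age,
                     gender = matched$gender, matched$w2, matched$scr2$items)
    if (!is.null(e1))
      w1 <- rbind(w1, data.frame(id = 1000000L + seq_len(extra1),
                                 age = e1$age, gender = e1$gender,
                                 e1$w1, e1$scr1$items))
    if (!is.null(e2))
      w2 <- rbind(w2, data.frame(id = 2000000L + seq_len(extra2),
                                 age = e2$age, gender = e2$gender,
                                 e2$w2, e2$scr2$items))
    list(wave1 = w1, wave2 = w2, truth = truth)
  })
}

#' Write a simulated panel or cohort to CSV (+ ground truth JSON)
#'
#' @param sim result of \code{\link{generate_panel}} or
#'   \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(sim, "clpn_sim")) {
    tabs <- as_wave_tables(sim$panel)
    truth <- sim$truth
  } else {
    tabs <- sim[c("wave1", "wave2")]
    truth <- sim$truth
  }
  p1 <- file.path(dir, "wave1.csv"); p2 <- file.path(dir, "wave2.csv")
  write.csv(tabs$wave1, p1, row.names = FALSE)
  write.csv(tabs$wave2, p2, row.names = FALSE)
  pt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(true_cross_lagged = unclass(truth$true_cross_lagged),
         true_autoregressive = truth$true_autoregressive,
         discretization_thresholds = truth$discretization_thresholds,
         hub_out = truth$hub_out, hub_in = truth$hub_in, seed = truth$seed),
    pt, digits = NA, auto_unbox = TRUE)
  invisible(c(wave1 = p1, wave2 = p2, ground_truth = pt))
}

#' @export
print.clpn_ground_truth <- function(x, ...) {
  cat("Ground truth for a synthetic cross-lagged panel\n")
  cat(sprintf("  items: %d, nonzero cross-lagged effects: %d\n",
              nrow(x$true_cross_lagged), sum(x$true_cross_lagged != 0)))
  if (length(x$hub_out)) cat("  planted OEI hub(s):", x$hub_out, "\n")
  if (length(x$hub_in)) cat("  planted IEI hub(s):", x$hub_in, "\n")
  invisible(x)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "Generator config: n = %d, %d items (%d levels), %d screener items\n",
    x$n_participants, x$n_items, x$likert_levels, x$n_screener_items))
  cat(sprintf("  latent wave-1 correlation %.2f, noise sd %.2f, seed %d\n",
              x$latent_wave1_correlation, x$noise_sd, x$seed))
  invisible(x)
}
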