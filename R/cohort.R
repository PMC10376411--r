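# Cohort handling: the symptom_panel container, CSV ingestion with schema
# and range validation, wave matching, screener-based subgroup selection,
# and the descriptive / paired-test / reliability statistics.

#' Matched two-wave symptom panel
#'
#' The universal input object: item scores for the same participants at two
#' waves, baseline covariates, and per-wave screener totals. Item matrices
#' must share row order; ordinal panels are range-checked against the
#' declared number of levels.
#'
#' @param ids participant keys (no duplicates).
#' @param age,gender baseline covariates (gender 0/1 coded).
#' @param wave1_items,wave2_items n x p item matrices.
#' @param wave1_screener,wave2_screener optional n x k screener item
#'   matrices (scored 0..screener_levels-1); totals are derived from them.
#' @param wave1_screener_total,wave2_screener_total totals, if item-level
#'   screener data are not available.
#' @param ordinal whether item scores are ordinal (range-checked) or
#'   continuous latent scores.
#' @param likert_levels,screener_levels declared category counts.
#' @return An object of class \code{symptom_panel}.
#' @export
symptom_panel <- function(ids, age, gender, wave1_items, wave2_items,
                          wave1_screener = NULL, wave2_screener = NULL,
                          wave1_screener_total = NULL,
                          wave2_screener_total = NULL,
                          ordinal = TRUE, likert_levels = 5L,
                          screener_levels = 4L) {
  wave1_items <- as.matrix(wave1_items)
  wave2_items <- as.matrix(wave2_items)
  n <- length(ids)
  if (anyDuplicated(ids)) stopf("duplicated participant keys")
  if (nrow(wave1_items) != n || nrow(wave2_items) != n ||
      ncol(wave1_items) != ncol(wave2_items))
    stopf("wave item matrices must share n = %d rows and one item count", n)
  if (length(age) != n || length(gender) != n)
    stopf("covariate length mismatch")
  if (ordinal && n > 0) {
    for (w in list(wave1 = wave1_items, wave2 = wave2_items)) {
      if (any(w != round(w)) || min(w) < 1 || max(w) > likert_levels)
        stopf("ordinal item scores must be integers in [1, %d]",
              likert_levels)
    }
  }
  tot <- function(scr, given, wave) {
    if (!is.null(scr)) {
      scr <- as.matrix(scr)
      if (nrow(scr) != n) stopf("%s screener rows != n", wave)
      if (n > 0 && (min(scr) < 0 || max(scr) > screener_levels - 1L))
        stopf("%s screener scores outside [0, %d]", wave,
              screener_levels - 1L)
      as.integer(rowSums(scr))
    } else if (!is.null(given)) as.integer(given) else NULL
  }
  obj <- list(ids = ids, age = age, gender = gender,
              wave1_items = wave1_items, wave2_items = wave2_items,
              wave1_screener = wave1_screener,
              wave2_screener = wave2_screener,
              wave1_screener_total = tot(wave1_screener,
                                         wave1_screener_total, "wave1"),
              wave2_screener_total = tot(wave2_screener,
                                         wave2_screener_total, "wave2"),
              ordinal = ordinal, likert_levels = as.integer(likert_levels),
              screener_levels = as.integer(screener_levels))
  class(obj) <- "symptom_panel"
  obj
}

#' @export
print.symptom_panel <- function(x, ...) {
  cat(sprintf("Two-wave symptom panel: n = %d participants, %d items%s\n",
              n_participants(x), ncol(x$wave1_items),
              if (x$ordinal) sprintf(" (1-%d)", x$likert_levels) else
                " (continuous)"))
  if (!is.null(x$wave1_screener_total))
    cat(sprintf("  screener totals: wave-1 mean %.2f, wave-2 mean %.2f\n",
                mean(x$wave1_screener_total), mean(x$wave2_screener_total)))
  invisible(x)
}

#' Number of participants in a panel
#' @param panel a \code{symptom_panel}.
#' @export
n_participants <- function(panel) length(panel$ids)

#' @export
`[.symptom_panel` <- function(x, i, ...) {
  sub <- function(m) if (is.null(m)) NULL else m[i, , drop = FALSE]
  out <- list(ids = x$ids[i], age = x$age[i], gender = x$gender[i],
              wave1_items = x$wave1_items[i, , drop = FALSE],
              wave2_items = x$wave2_items[i, , drop = FALSE],
              wave1_screener = sub(x$wave1_screener),
              wave2_screener = sub(x$wave2_screener),
              wave1_screener_total = x$wave1_screener_total[i],
              wave2_screener_total = x$wave2_screener_total[i],
              ordinal = x$ordinal, likert_levels = x$likert_levels,
              screener_levels = x$screener_levels)
  class(out) <- "symptom_panel"
  out
}

#' Turn a panel back into raw wave tables
#' @param panel a \code{symptom_panel} with item-level screener data.
#' @return List of two data frames following the CSV schema.
#' @export
as_wave_tables <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  mk <- function(items, scr) {
    df <- data.frame(id = panel$ids, age = panel$age, gender = panel$gender)
    cbind(df, as.data.frame(items), as.data.frame(scr))
  }
  list(wave1 = mk(panel$wave1_items, panel$wave1_screener),
       wave2 = mk(panel$wave2_items, panel$wave2_screener))
}

# Validate one raw wave table against the declared schema.
.validate_wave_table <- function(df, wave, n_items, n_screener_items,
                                 item_prefix, screener_prefix, key) {
  need <- c(key, "age", "gender",
            paste0(item_prefix, seq_len(n_items)),
            paste0(screener_prefix, seq_len(n_screener_items)))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("%s: schema error, missing column(s): %s", wave,
          paste(missing, collapse = ", "))
  if (nrow(df) == 0) stopf("%s: schema error, no data rows", wave)
  bad <- character(0)
  for (col in paste0(item_prefix, seq_len(n_items))) {
    v <- df[[col]]
    off <- which(!is.finite(v) | v < 1 | v > 5 | v != round(v))
    if (length(off))
      bad <- c(bad, sprintf("%s rows %s", col,
                            paste(head(off, 5), collapse = ",")))
  }
  for (col in paste0(screener_prefix, seq_len(n_screener_items))) {
    v <- df[[col]]
    off <- which(!is.finite(v) | v < 0 | v > 3 | v != round(v))
    if (length(off))
      bad <- c(bad, sprintf("%s rows %s", col,
                            paste(head(off, 5), collapse = ",")))
  }
  if (length(bad))
    stopf("%s: out-of-range item scores: %s", wave,
          paste(bad, collapse = "; "))
  df
}

#' Read and validate raw two-wave CSV tables
#'
#' Expects the schema \code{id, age, gender, iat1..iat20, phq1..phq9}
#' (prefixes and counts configurable). Item scores must be integers in
#' [1, 5] and screener scores in [0, 3]; violations are reported with the
#' offending column and row numbers.
#'
#' @param wave1_path,wave2_path CSV file paths.
#' @param n_items,n_screener_items expected column counts.
#' @param item_prefix,screener_prefix column-name prefixes.
#' @param key name of the participant key column.
#' @return List with validated \code{wave1} and \code{wave2} data frames.
#' @export
read_panel <- function(wave1_path, wave2_path, n_items = 20L,
                       n_screener_items = 9L, item_prefix = "iat",
                       screener_prefix = "phq", key = "id") {
  for (pth in c(wave1_path, wave2_path))
    if (!file.exists(pth)) stopf("file not found: %s", pth)
  rd <- function(pth, wave) {
    df <- tryCatch(read.csv(pth), error = function(e)
      stopf("%s: schema error, cannot parse %s (%s)", wave, pth,
            conditionMessage(e)))
    .validate_wave_table(df, wave, n_items, n_screener_items,
                         item_prefix, screener_prefix, key)
  }
  list(wave1 = rd(wave1_path, "wave1"), wave2 = rd(wave2_path, "wave2"))
}

#' Match two wave tables on a participant key
#'
#' Inner-joins the waves on \code{key}; participants observed in only one
#' wave are dropped and counted. Output rows are sorted by key. Covariates
#' (age, gender) are taken from the wave-1 table.
#'
#' @param w1,w2 raw wave tables (data frames).
#' @param key participant key column name.
#' @param item_prefix,screener_prefix column-name prefixes.
#' @return A \code{\link{symptom_panel}} with attributes
#'   \code{dropped_wave1} / \code{dropped_wave2} (counts of unmatched rows).
#' @export
match_waves <- function(w1, w2, key = "id", item_prefix = "iat",
                        screener_prefix = "phq") {
  if (!key %in% names(w1) || !key %in% names(w2))
    stopf("key column '%s' missing", key)
  if (anyDuplicated(w1[[key]]))
    stopf("duplicate keys within wave 1: ambiguous match")
  if (anyDuplicated(w2[[key]]))
    stopf("duplicate keys within wave 2: ambiguous match")
  shared <- sort(intersect(w1[[key]], w2[[key]]))
  d1 <- nrow(w1) - length(shared)
  d2 <- nrow(w2) - length(shared)
  if (length(shared) == 0) warnf("no shared keys: empty panel")
  i1 <- match(shared, w1[[key]])
  i2 <- match(shared, w2[[key]])
  icols <- grep(paste0("^", item_prefix, "[0-9]+$"), names(w1), value = TRUE)
  icols <- icols[order(as.integer(sub(item_prefix, "", icols)))]
  scols <- grep(paste0("^", screener_prefix, "[0-9]+$"), names(w1),
                value = TRUE)
  scols <- scols[order(as.integer(sub(screener_prefix, "", scols)))]
  panel <- symptom_panel(
    ids = shared,
    age = w1$age[i1], gender = w1$gender[i1],
    wave1_items = as.matrix(w1[i1, icols]),
    wave2_items = as.matrix(w2[i2, icols]),
    wave1_screener = if (length(scols)) as.matrix(w1[i1, scols]) else NULL,
    wave2_screener = if (length(scols)) as.matrix(w2[i2, scols]) else NULL)
  attr(panel, "dropped_wave1") <- d1
  attr(panel, "dropped_wave2") <- d2
  panel
}

#' Screen a panel on the wave-1 screener total
#'
#' Retains participants whose wave-1 screener total reaches \code{cutoff}
#' and reports per-wave prevalence of scores at or above the cutoff
#' (percent of the full panel, rounded to 2 decimals for reporting).
#'
#' @param panel a \code{\link{symptom_panel}} with screener totals.
#' @param cutoff integer cutoff in [0, 27].
#' @return List with \code{panel} (the screened subset),
#'   \code{prevalence_w1}, \code{prevalence_w2} (percent),
#'   \code{n_positive_w1}, \code{n_positive_w2}, \code{n_total}, and
#'   \code{cutoff}.
#' @export
screen_panel <- function(panel, cutoff = 8L) {
  stopifnot(inherits(panel, "symptom_panel"))
  if (!is_count(cutoff) || cutoff > 27)
    stopf("`cutoff` must be an integer in [0, 27], got %s", cutoff)
  if (is.null(panel$wave1_screener_total))
    stopf("panel has no screener totals")
  n <- n_participants(panel)
  pos1 <- panel$wave1_screener_total >= cutoff
  pos2 <- panel$wave2_screener_total >= cutoff
  list(panel = panel[which(pos1)],
       prevalence_w1 = round(100 * sum(pos1) / n, 2),
       prevalence_w2 = round(100 * sum(pos2) / n, 2),
       n_positive_w1 = sum(pos1), n_positive_w2 = sum(pos2),
       n_total = n, cutoff = as.integer(cutoff))
}

# Sample skewness g1 and excess kurtosis g2 (moment estimators, no
# small-sample adjustment; these are inspection-only outputs).
.skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}
.kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}

#' Per-item descriptive and paired-test table
#'
#' For each item: means, SDs (n-1 denominator), skewness and excess
#' kurtosis at both waves; the paired t test on (wave2 - wave1) with its
#' df and p; the mean difference with a t-based 95 percent CI; and the
#' paired effect size Cohen's dz = t / sqrt(n) with a normal-approximation
#' CI (SE = sqrt(1/n + dz^2 / (2n))). Items whose difference scores have
#' zero variance get an NA t and a note in \code{t_undefined}.
#'
#' @param panel a \code{\link{symptom_panel}} with n >= 3.
#' @return Data frame with one row per item (class
#'   \code{clpn_descriptives}).
#' @export
descriptives_table <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  n <- n_participants(panel)
  if (n < 3) stopf("need n >= 3, got %d", n)
  items <- colnames(panel$wave1_items)
  if (is.null(items)) items <- paste0("item", seq_len(ncol(panel$wave1_items)))
  rows <- lapply(seq_along(items), function(j) {
    x1 <- panel$wave1_items[, j]
    x2 <- panel$wave2_items[, j]
    d <- x2 - x1
    und <- sd(d) == 0
    if (und) {
      tt <- NA_real_; pv <- NA_real_; ci <- c(NA_real_, NA_real_)
      dz <- NA_real_; dci <- c(NA_real_, NA_real_)
    } else {
      ht <- t.test(d)
      tt <- unname(ht$statistic); pv <- ht$p.value; ci <- ht$conf.int
      dz <- tt / sqrt(n)
      se_d <- sqrt(1 / n + dz^2 / (2 * n))
      dci <- dz + c(-1, 1) * qnorm(0.975) * se_d
    }
    data.frame(item = items[j],
               mean_w1 = mean(x1), sd_w1 = sd(x1),
               skewness_w1 = .skewness(x1), kurtosis_w1 = .kurtosis(x1),
               mean_w2 = mean(x2), sd_w2 = sd(x2),
               skewness_w2 = .skewness(x2), kurtosis_w2 = .kurtosis(x2),
               t_statistic = tt, df = n - 1L, p_value = pv,
               mean_difference = mean(d),
               diff_ci_lower = ci[1], diff_ci_upper = ci[2],
               cohens_dz = dz, d_ci_lower = dci[1], d_ci_upper = dci[2],
               t_undefined = und)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("clpn_descriptives", class(out))
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \code{alpha = k/(k-1) * (1 - sum(item variances) / variance(total))},
#' variances with n-1 denominator.
#'
#' @param items numeric matrix (n x k), k >= 2, n >= 3.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items); n <- nrow(items)
  if (k < 2) stopf("need at least 2 items")
  if (n < 3) stopf("need at least 3 observations")
  vt <- var(rowSums(items))
  if (vt == 0) stopf("zero total-score variance: alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, var)) / vt)
}
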