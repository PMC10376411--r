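# End-to-end orchestration: generate or read data, match and screen,
# describe, estimate the cross-lagged network with centralities, compare
# the per-wave cross-sectional networks, run the stability/accuracy
# bootstraps and the matrix-correlation sensitivity check, and write every
# artifact to an output directory with a summary that suffices to re-run
# the pipeline identically.

#' Pipeline configuration
#'
#' Exactly one of \code{input} (paths to wave CSVs) or \code{generator}
#' (arguments for \code{\link{generator_config}}, plus optional
#' \code{n_wave1}/\code{n_wave2}/\code{n_matched} for a partially
#' overlapping cohort) must be given.
#'
#' @param input list with \code{wave1} and \code{wave2} CSV paths, or NULL.
#' @param generator list of generator arguments, or NULL.
#' @param cutoff screener cutoff (integer in [0, 27], default 8).
#' @param estimation list: \code{n_folds}, \code{lambda_rule},
#'   \code{n_lambda}, \code{include_covariates}.
#' @param nct list: \code{n_permutations}, \code{paired}.
#' @param resampling list: \code{n_boot}, \code{drop_proportions},
#'   \code{n_boot_ci}.
#' @param out_dir output directory.
#' @param seed master seed; fans out to named child streams per stage.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, generator = NULL, cutoff = 8L,
                            estimation = list(), nct = list(),
                            resampling = list(), out_dir = "clpnet-out",
                            seed = 1L) {
  if (is.null(input) == is.null(generator))
    stopf("exactly one of `input` and `generator` must be given")
  if (!is_count(cutoff) || cutoff > 27)
    stopf("`cutoff` must be an integer in [0, 27]")
  est <- utils::modifyList(list(n_folds = 10L, lambda_rule = "min",
                                n_lambda = 100L, include_covariates = TRUE),
                           estimation)
  nct <- utils::modifyList(list(n_permutations = 1000L, paired = TRUE), nct)
  res <- utils::modifyList(list(n_boot = 1000L,
                                drop_proportions = seq(0.05, 0.75, 0.05),
                                n_boot_ci = 1000L), resampling)
  for (nm in c("n_folds", "n_lambda")) if (est[[nm]] < 1)
    stopf("estimation$%s must be positive", nm)
  if (nct$n_permutations < 20) stopf("nct$n_permutations must be >= 20")
  if (res$n_boot < 1 || res$n_boot_ci < 1)
    stopf("resampling counts must be positive")
  structure(list(input = input, generator = generator,
                 cutoff = as.integer(cutoff), estimation = est, nct = nct,
                 resampling = res, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys match the arguments of
#'   \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: \code{data} (generate or read + match),
#' \code{screen}, \code{describe}, \code{estimate} (CLPN + centrality),
#' \code{compare} (per-wave cross-sectional networks + NCT),
#' \code{stability} (case-dropping + edge CIs), \code{sensitivity}
#' (matrix correlations). Every artifact is written under
#' \code{config$out_dir} and logged; \code{summary.json} echoes the config
#' and seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param stages character vector of stages to run (\code{"all"} for the
#'   full sequence; earlier stages a later one depends on always run).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config, stages = "all", quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("data", "screen", "describe", "estimate", "compare",
                  "stability", "sensitivity")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  paths <- character(0)
  put <- function(name) {
    pth <- file.path(config$out_dir, name)
    paths[[name]] <<- pth
    say("writing %s", pth)
    pth
  }
  out <- list()

  # -- data ------------------------------------------------------------
  truth <- NULL
  lost1 <- lost2 <- NULL
  if (!is.null(config$generator)) {
    g <- config$generator
    gargs <- g[setdiff(names(g), c("n_wave1", "n_wave2", "n_matched"))]
    if (is.null(gargs$seed)) gargs$seed <- child_seed(config$seed, 101L)
    if (!is.null(g$n_wave1)) {
      gargs$n_participants <- g$n_matched
      cfg <- do.call(generator_config, gargs)
      cohort <- simulate_cohort(g$n_wave1, g$n_wave2, g$n_matched, cfg)
      tabs <- cohort; truth <- cohort$truth
    } else {
      cfg <- do.call(generator_config, gargs)
      sim <- generate_panel(cfg)
      tabs <- as_wave_tables(sim$panel); truth <- sim$truth
    }
    write_panel(if (!is.null(g$n_wave1)) cohort else
      structure(list(panel = sim$panel, truth = truth), class = "clpn_sim"),
      config$out_dir)
    paths[["wave1.csv"]] <- file.path(config$out_dir, "wave1.csv")
    paths[["wave2.csv"]] <- file.path(config$out_dir, "wave2.csv")
    w1 <- tabs$wave1; w2 <- tabs$wave2
  } else {
    raw <- read_panel(config$input$wave1, config$input$wave2)
    w1 <- raw$wave1; w2 <- raw$wave2
  }
  panel <- match_waves(w1, w2)
  say("matched panel: n = %d (dropped %d / %d unmatched rows)",
      n_participants(panel), attr(panel, "dropped_wave1"),
      attr(panel, "dropped_wave2"))
  out$panel <- panel
  out$truth <- truth
  if (identical(stages, "data")) return(invisible(out))

  # -- screen ----------------------------------------------------------
  scr <- screen_panel(panel, config$cutoff)
  out$screening <- scr
  say("screening at cutoff %d: prevalence %.2f%% (wave 1), %.2f%% (wave 2)",
      config$cutoff, scr$prevalence_w1, scr$prevalence_w2)
  jsonlite::write_json(
    list(cutoff = scr$cutoff, n_total = scr$n_total,
         n_positive_w1 = scr$n_positive_w1,
         n_positive_w2 = scr$n_positive_w2,
         prevalence_w1 = scr$prevalence_w1,
         prevalence_w2 = scr$prevalence_w2),
    put("screening.json"), auto_unbox = TRUE, digits = NA)
  sub <- scr$panel

  # -- describe --------------------------------------------------------
  if ("describe" %in% stages) {
    desc <- descriptives_table(sub)
    out$descriptives <- desc
    out$alpha <- c(wave1 = cronbach_alpha(sub$wave1_items),
                   wave2 = cronbach_alpha(sub$wave2_items))
    write.csv(desc, put("descriptives.csv"), row.names = FALSE)
  }

  # -- estimate --------------------------------------------------------
  net <- NULL
  if (any(c("estimate", "stability") %in% stages)) {
    net <- estimate_clpn(sub,
                         include_covariates =
                           config$estimation$include_covariates,
                         n_folds = config$estimation$n_folds,
                         n_lambda = config$estimation$n_lambda,
                         lambda_rule = config$estimation$lambda_rule,
                         seed = child_seed(config$seed, 102L))
    out$clpn <- net
    out$centrality <- centrality_table(net)
    out$edge_density <- edge_density(net)
    say("CLPN: %d of %d edges nonzero (%.1f%%)",
        out$edge_density$n_nonzero, out$edge_density$n_possible,
        out$edge_density$density_pct)
    write_network_csv(net, put("clpn_matrix.csv"))
    write_edge_list(net, put("clpn_edges.csv"))
    write.csv(out$centrality, put("centrality.csv"), row.names = FALSE)
    jsonlite::write_json(rank_report(out$centrality, k = 5L),
                         put("centrality_top.json"), digits = NA,
                         dataframe = "rows")
  }

  # -- compare ---------------------------------------------------------
  if ("compare" %in% stages) {
    nct <- nct_paired(sub$wave1_items, sub$wave2_items,
                      n_permutations = config$nct$n_permutations,
                      paired = config$nct$paired,
                      seed = child_seed(config$seed, 103L))
    out$nct <- nct
    say("NCT: S = %.2f (p = %.3f), M = %.2f (p = %.3f)",
        nct$s_diff, nct$p_global, nct$m_statistic, nct$p_structure)
    jsonlite::write_json(
      list(global_strength_a = nct$global_strength_a,
           global_strength_b = nct$global_strength_b,
           s_diff = nct$s_diff, p_global = nct$p_global,
           m_statistic = nct$m_statistic, p_structure = nct$p_structure,
           n_permutations = nct$n_permutations, paired = nct$paired,
           seed = nct$seed),
      put("nct.json"), auto_unbox = TRUE, digits = NA)
    write.csv(as.data.frame(nct$edge_p_values), put("nct_edge_p.csv"))
  }

  # -- stability -------------------------------------------------------
  if ("stability" %in% stages) {
    stab <- case_dropping_bootstrap(
      sub, drop_proportions = config$resampling$drop_proportions,
      n_boot = config$resampling$n_boot,
      seed = child_seed(config$seed, 104L))
    out$stability <- stab
    out$cs <- cs_coefficient(stab)
    say("CS-coefficients: %s",
        paste(sprintf("%s = %.2f", names(out$cs), out$cs), collapse = ", "))
    stability_long(stab, put("stability_curves.csv"))
    jsonlite::write_json(as.list(out$cs), put("cs_coefficients.json"),
                         auto_unbox = TRUE, digits = NA)
    eb <- edge_ci_bootstrap(sub, n_boot = config$resampling$n_boot_ci,
                            seed = child_seed(config$seed, 105L))
    out$edge_boot <- eb
    ew <- data.frame(edge = as.vector(outer(rownames(eb$sample_weights),
                                            colnames(eb$sample_weights),
                                            paste, sep = "->")),
                     weight = as.numeric(eb$sample_weights),
                     ci_lower = as.numeric(eb$ci_lower),
                     ci_upper = as.numeric(eb$ci_upper))
    write.csv(ew, put("edge_ci.csv"), row.names = FALSE)
  }

  # -- sensitivity -----------------------------------------------------
  if ("sensitivity" %in% stages) {
    # matched vs unmatched ("lost") rows, per wave, when the cohort has
    # unmatched rows; otherwise wave-1 vs wave-2 matched networks
    m1 <- estimate_cs_network(panel$wave1_items)
    m2 <- estimate_cs_network(panel$wave2_items)
    only1 <- !(w1$id %in% panel$ids)
    only2 <- !(w2$id %in% panel$ids)
    icols <- colnames(panel$wave1_items)
    sens <- list()
    if (sum(only1) >= 3 * ncol(panel$wave1_items)) {
      l1 <- estimate_cs_network(as.matrix(w1[only1, icols]))
      sens$wave1_matched_vs_lost <- network_correlation(m1, l1)
    }
    if (sum(only2) >= 3 * ncol(panel$wave2_items)) {
      l2 <- estimate_cs_network(as.matrix(w2[only2, icols]))
      sens$wave2_matched_vs_lost <- network_correlation(m2, l2)
    }
    sens$wave1_vs_wave2_matched <- network_correlation(m1, m2)
    out$sensitivity <- sens
    say("sensitivity correlations: %s",
        paste(sprintf("%s = %.2f", names(sens), unlist(sens)),
              collapse = ", "))
    jsonlite::write_json(sens, put("sensitivity.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  # -- summary ---------------------------------------------------------
  cfg_echo <- unclass(config)
  cfg_echo$generator$true_cross_lagged <- NULL  # matrices go to ground_truth
  jsonlite::write_json(list(config = cfg_echo, seed = config$seed,
                            stages = stages, outputs = as.list(paths)),
                       put("summary.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  out$paths <- paths
  invisible(out)
}
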