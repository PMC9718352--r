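#' The theory-prediction table
#'
#' One row per (experiment, theory) cell in which a theory makes a
#' prediction: experiment 1 -- aversive discounting predicts LL, utility from
#' anticipation predicts EL; experiment 2 -- only utility from anticipation
#' predicts (EE); experiment 3 -- both predict EE. `p_axis` is the Bernoulli
#' rate on the plotted axis used by [run_simulated_predictions()]: the
#' simulated cohort prefers the predicted option at 0.6, and the plotted
#' fraction is that of the design's second option, so cells whose predicted
#' option is the first (reported) option appear at 0.4.
#'
#' @return A data.frame with columns `experiment_id`, `theory`,
#'   `predicted_option`, `p_axis`.
#' @export
prediction_table <- function() {
  cells <- data.frame(
    experiment_id = c(1L, 1L, 2L, 3L, 3L),
    theory = c("aversive_discounting", "utility_from_anticipation",
               "utility_from_anticipation", "aversive_discounting",
               "utility_from_anticipation"),
    predicted_option = c("LL", "EL", "EE", "EE", "EE"),
    stringsAsFactors = FALSE)
  cells$p_axis <- vapply(seq_len(nrow(cells)), function(i) {
    d <- experiment_design(cells$experiment_id[i])
    if (cells$predicted_option[i] == d$option_b$label) 0.6 else 0.4
  }, numeric(1))
  cells
}

#' Simulate the quantitative theory predictions
#'
#' For every cell of [prediction_table()], generates a fixed-rate Bernoulli
#' cohort expressing the predicted preference (0.6 toward the predicted
#' option), fits the hierarchical Bernoulli-beta model and records the
#' posterior mean and 95\% HDI of the group-level probability together with
#' convergence diagnostics. Non-convergent cells (R-hat >= `rhat_max`) are
#' flagged, not retried, so runs stay reproducible.
#'
#' @param n_subjects Cohort size per cell; `NULL` (default) uses the
#'   experiment's group size (25, 20, 21).
#' @param chains,iter,warmup MCMC settings per cell.
#' @param seed Integer seed; each cell derives its own sub-seed.
#' @param rhat_max Convergence flag threshold.
#' @return Data.frame, one row per cell: `experiment_id`, `theory`,
#'   `predicted_option`, `p_generate`, `mu_mean`, `hdi_lower`, `hdi_upper`,
#'   `rhat_mu`, `ess_mu`, `converged`.
#' @export
run_simulated_predictions <- function(n_subjects = NULL, chains = 4,
                                      iter = 5000, warmup = 1000,
                                      seed = 1, rhat_max = 1.05) {
  cells <- prediction_table()
  group_sizes <- c(25L, 20L, 21L)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ns <- if (is.null(n_subjects)) group_sizes[cells$experiment_id[i]]
          else n_subjects
    design <- experiment_design(cells$experiment_id[i])
    spec <- cohort_spec(n_subjects = ns, p_choice = cells$p_axis[i],
                        omission_rate =
                          omission_rate_default(cells$experiment_id[i]),
                        seed = seed + 101L * i)
    tab <- generate_binomial_cohort(spec, design)
    fit <- bernbeta(tab, chains = chains, iter = iter, warmup = warmup,
                    seed = seed + 101L * i + 1L)
    s <- summary(fit, check_convergence = FALSE)
    data.frame(
      experiment_id = cells$experiment_id[i], theory = cells$theory[i],
      predicted_option = cells$predicted_option[i],
      p_generate = cells$p_axis[i],
      mu_mean = s$mu_mean, hdi_lower = s$mu_hdi[1], hdi_upper = s$mu_hdi[2],
      rhat_mu = s$params["mu", "rhat"], ess_mu = s$params["mu", "ess"],
      converged = s$params["mu", "rhat"] < rhat_max,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full analysis of one experiment's trial table
#'
#' Runs the complete inferential battery on a trial-level choice log: the
#' per-subject choice fractions, the one-sample t test against 50\%, the
#' hierarchical Bayesian fit with HDI, and the indifference check (does the
#' 95\% HDI of the group mean exclude 0.5?).
#'
#' @param table A [trial_table()].
#' @param chains,iter,warmup,seed MCMC settings.
#' @return An object of class `dread_report`: list with `fractions`,
#'   `ttest`, `posterior` (a `summary.bernbeta`), `hdi_excludes_chance` and
#'   `agreement` (do the frequentist and Bayesian routes point the same
#'   way?).
#' @export
run_experiment_analysis <- function(table, chains = 4, iter = 5000,
                                    warmup = 1000, seed = 1) {
  stopifnot(inherits(table, "trial_table"))
  fractions <- choice_fractions(table)
  tt <- one_sample_t(fractions$fraction_target)
  fit <- bernbeta(table, chains = chains, iter = iter, warmup = warmup,
                  seed = seed)
  s <- summary(fit, check_convergence = FALSE)
  excludes <- s$mu_hdi[1] > 0.5 || s$mu_hdi[2] < 0.5
  structure(
    list(fractions = fractions, ttest = tt, posterior = s,
         hdi_excludes_chance = excludes,
         agreement = sign(s$mu_mean - 0.5) ==
           sign(mean(fractions$fraction_target, na.rm = TRUE) - 50)),
    class = "dread_report")
}

#' @export
print.dread_report <- function(x, ...) {
  cat("=== Choice analysis report ===\n")
  print(x$ttest)
  cat(sprintf("Bayesian group mean: %.3f, 95%% HDI (%.3f, %.3f) -- %s 0.5\n",
              x$posterior$mu_mean, x$posterior$mu_hdi[1],
              x$posterior$mu_hdi[2],
              if (x$hdi_excludes_chance) "excludes" else "contains"))
  if (!x$posterior$converged) cat("warning: convergence suspect\n")
  invisible(x)
}

#' Loader for the published per-subject choice tables
#'
#' The original study deposited its raw data and scripts as a ZIP archive.
#' This loader reads, once the user has extracted such an archive, a CSV of
#' per-subject choice percentages with columns `experiment_id, subject_id,
#' percent_target` (one row per animal; the mapping from the archive's
#' native layout to this schema must be done by the user, as documented in
#' the README). When the file is absent the loader reports that cleanly and
#' returns `NULL`, so analyses depending on the published data degrade
#' gracefully.
#'
#' @param path Path to the prepared CSV.
#' @return Data.frame with one row per animal, or `NULL` (with a message) if
#'   `path` does not exist.
#' @export
load_extended_data <- function(path) {
  if (!file.exists(path)) {
    message("published choice data not found at '", path,
            "'; supply the extracted archive to run supplementary checks")
    return(NULL)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "subject_id", "percent_target")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ", "))
  if (any(df$percent_target < 0 | df$percent_target > 100))
    stop("percent_target must lie in [0, 100]")
  df
}
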