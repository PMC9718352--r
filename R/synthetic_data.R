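#' Specification of a simulated cohort
#'
#' Defaults mirror the task: 10 sessions per subject, each of 6 forced trials
#' (3 per arm, order randomised) followed by 16 free trials. In fixed-rate
#' mode every free choice is an independent Bernoulli draw of the target
#' option at `p_choice`; in agent mode (see [simulate_experiment()])
#' `p_choice` is derived from a decision theory through the softmax rule.
#' Omission trials (the animal leaves the arm before the shock) occur at
#' `omission_rate` per free trial and record no choice.
#'
#' @param n_subjects Number of subjects (the standard cohorts are 25, 20 and
#'   21 for experiments 1-3).
#' @param p_choice Probability of choosing the target option on a free trial
#'   (fixed-rate mode).
#' @param n_sessions,n_free_per_session,n_forced_per_session Session
#'   structure; defaults 10, 16, 6.
#' @param omission_rate Per-free-trial omission probability (observed rates
#'   in the task are below 1\%; defaults per experiment are 0.0080, 0.0002
#'   and 0.0013 -- see [omission_rate_default()]).
#' @param seed Integer seed; the whole table is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, p_choice, n_sessions = 10,
                        n_free_per_session = 16, n_forced_per_session = 6,
                        omission_rate = 0, seed = NULL) {
  stopifnot(n_subjects >= 1, n_sessions >= 1,
            n_free_per_session >= 0, n_forced_per_session >= 0)
  if (p_choice < 0 || p_choice > 1) stop("p_choice must lie in [0, 1]")
  if (omission_rate < 0 || omission_rate > 1)
    stop("omission_rate must lie in [0, 1]")
  if (n_forced_per_session %% 2 != 0)
    stop("n_forced_per_session must be even (equal sampling of both arms)")
  structure(
    list(n_subjects = as.integer(n_subjects), p_choice = p_choice,
         n_sessions = as.integer(n_sessions),
         n_free_per_session = as.integer(n_free_per_session),
         n_forced_per_session = as.integer(n_forced_per_session),
         omission_rate = omission_rate, seed = seed),
    class = "cohort_spec")
}

#' Observed omission rates per experiment
#'
#' The fractions of free trials on which animals left the arm before the
#' shock: 0.80\%, 0.02\% and 0.13\% in experiments 1-3.
#'
#' @param experiment_id 1, 2 or 3.
#' @return Omission probability per free trial.
#' @export
omission_rate_default <- function(experiment_id) {
  stopifnot(experiment_id %in% 1:3)
  c(0.0080, 0.0002, 0.0013)[experiment_id]
}

#' Pseudo-random arm-contingency schedule
#'
#' Assigns the target option to the left or right arm for each session.
#' Contingencies are pseudo-randomised with a forced reversal: if a side
#' persisted for two consecutive sessions it is reversed in the next, so no
#' side ever runs longer than two sessions and the animal must re-learn the
#' arm-outcome mapping.
#'
#' @param n_sessions Number of sessions (>= 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Character vector of `"left"`/`"right"`, one per session.
#' @examples
#' contingency_schedule(10, seed = 1)
#' @export
contingency_schedule <- function(n_sessions, seed = NULL) {
  stopifnot(n_sessions >= 1)
  if (!is.null(seed)) set.seed(seed)
  sides <- character(n_sessions)
  sides[1] <- sample(c("left", "right"), 1)
  for (i in seq_len(n_sessions)[-1]) {
    if (i >= 3 && sides[i - 1] == sides[i - 2])
      sides[i] <- setdiff(c("left", "right"), sides[i - 1])
    else
      sides[i] <- sample(c("left", "right"), 1)
  }
  sides
}

# Build one subject's rows given a per-trial Bernoulli rate of choosing the
# target option. Forced trials split 3/3 across the arms in random order and
# are always completed; omissions occur on free trials only.
simulate_subject <- function(subject_id, design, p_choice, spec) {
  labels <- design_labels(design)
  target <- design$target_option
  other <- setdiff(labels, target)
  schedule <- contingency_schedule(spec$n_sessions)
  offered_free <- paste(labels, collapse = "|")
  n_forced <- spec$n_forced_per_session
  n_free <- spec$n_free_per_session
  rows <- vector("list", spec$n_sessions)
  for (ses in seq_len(spec$n_sessions)) {
    forced_opts <- sample(rep(labels, each = n_forced %/% 2))
    omit <- stats::runif(n_free) < spec$omission_rate
    pick_target <- stats::runif(n_free) < p_choice
    chosen_free <- ifelse(omit, NA_character_,
                          ifelse(pick_target, target, other))
    rows[[ses]] <- data.frame(
      experiment_id = design$experiment_id,
      subject_id = subject_id,
      session = ses,
      trial_index = seq_len(n_forced + n_free),
      trial_type = c(rep("forced", n_forced), rep("free", n_free)),
      offered = c(forced_opts, rep(offered_free, n_free)),
      chosen = c(forced_opts, chosen_free),
      omission = c(rep(FALSE, n_forced), omit),
      side_of_target = schedule[ses],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a fixed-rate Bernoulli cohort
#'
#' Every subject chooses the target option on each valid free trial with the
#' same probability `spec$p_choice`, independently across trials -- the
#' random-binomial construction used to simulate theory predictions
#' quantitatively. Session structure, forced-trial split and the
#' contingency-reversal schedule follow the task.
#'
#' @param spec A [cohort_spec()] in fixed-rate mode.
#' @param design An [experiment_design()].
#' @return A [trial_table()].
#' @examples
#' tab <- generate_binomial_cohort(
#'   cohort_spec(n_subjects = 3, p_choice = 0.6, seed = 42),
#'   experiment_design(1))
#' choice_fractions(tab)
#' @export
generate_binomial_cohort <- function(spec, design) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "experiment_design"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ids <- sprintf("s%02d", seq_len(spec$n_subjects))
  rows <- lapply(ids, simulate_subject, design = design,
                 p_choice = spec$p_choice, spec = spec)
  trial_table(do.call(rbind, rows), design)
}

#' Simulate an experiment with theory-driven agents
#'
#' Each agent evaluates both arms under the supplied decision theory; on
#' every free trial it chooses the target option with probability
#' `choice_probability(U_target, U_other, temperature)`. The trial skeleton
#' (forced/free structure, contingency schedule, omissions) is identical to
#' [generate_binomial_cohort()].
#'
#' @param design An [experiment_design()].
#' @param params A [theory_params()].
#' @param spec A [cohort_spec()]; its `p_choice` is ignored in agent mode.
#' @return A [trial_table()].
#' @examples
#' tab <- simulate_experiment(experiment_design(1),
#'                            theory_params("aversive_discounting"),
#'                            cohort_spec(n_subjects = 3, p_choice = 0.5,
#'                                        seed = 7))
#' @export
simulate_experiment <- function(design, params, spec) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "theory_params"),
            inherits(spec, "cohort_spec"))
  target <- design$target_option
  opts <- list(design$option_a, design$option_b)
  u <- vapply(opts, option_utility, numeric(1), params = params)
  is_target <- design_labels(design) == target
  p_target <- choice_probability(u[is_target], u[!is_target],
                                 params$temperature)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ids <- sprintf("s%02d", seq_len(spec$n_subjects))
  rows <- lapply(ids, simulate_subject, design = design,
                 p_choice = p_target, spec = spec)
  trial_table(do.call(rbind, rows), design)
}
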