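#' Option specification for one T-maze arm
#'
#' Describes the outcome contingency attached to one decision arm: the delay
#' from arm entry to the electric shock, the delay from arm entry to the food
#' reward, the reward magnitude, and whether a shock is delivered at all.
#' Delays in the standard task are drawn from \{1, 2, 20, 21\} seconds
#' (early/late shock at 1/20 s, early/late reward at 2/21 s).
#'
#' @param label Option label, one of `"EL"` (early shock + late reward),
#'   `"LL"` (late shock + late reward), `"EE"` (early shock + early reward).
#' @param shock_delay Seconds from arm entry to shock (>= 0).
#' @param reward_delay Seconds from arm entry to reward (> 0).
#' @param reward_magnitude Number of sucrose pellets (default 3).
#' @param shock_present Logical; is a shock delivered in this arm?
#' @return An object of class `option_spec`.
#' @examples
#' option_spec("EL", shock_delay = 1, reward_delay = 21)
#' @export
option_spec <- function(label, shock_delay, reward_delay,
                        reward_magnitude = 3, shock_present = TRUE) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(shock_delay) || shock_delay < 0)
    stop("shock_delay must be a non-negative number of seconds")
  if (!is.numeric(reward_delay) || reward_delay <= 0)
    stop("reward_delay must be a positive number of seconds")
  structure(
    list(label = label, shock_delay = shock_delay,
         reward_delay = reward_delay, reward_magnitude = reward_magnitude,
         shock_present = isTRUE(shock_present)),
    class = "option_spec")
}

#' Experimental design: two arms and the reported option
#'
#' The three canonical designs offer the following pairs (delays are seconds
#' from arm entry):
#' \describe{
#'   \item{Experiment 1}{EL (shock 1 s, reward 21 s) vs LL (shock 20 s,
#'     reward 21 s); choice percentages are reported for EL.}
#'   \item{Experiment 2}{EE (shock 1 s, reward 2 s) vs LL (shock 20 s,
#'     reward 21 s); reported for EE. The shock-to-reward interval is 1 s in
#'     both arms.}
#'   \item{Experiment 3}{EE (shock 1 s, reward 2 s) vs EL (shock 1 s,
#'     reward 21 s); reported for EE. Entry-to-shock delay is identical.}
#' }
#'
#' @param experiment_id 1, 2 or 3 selects a canonical design; custom designs
#'   can be built by supplying `option_a`, `option_b` and `target_option`.
#' @param option_a,option_b [option_spec()] objects (override the canonical
#'   pair).
#' @param target_option Label of the option whose choice fraction is the
#'   dependent variable.
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design(1)
#' @export
experiment_design <- function(experiment_id, option_a = NULL, option_b = NULL,
                              target_option = NULL) {
  stopifnot(length(experiment_id) == 1L, experiment_id %in% 1:3 ||
              (!is.null(option_a) && !is.null(option_b)))
  el <- option_spec("EL", shock_delay = 1,  reward_delay = 21)
  ll <- option_spec("LL", shock_delay = 20, reward_delay = 21)
  ee <- option_spec("EE", shock_delay = 1,  reward_delay = 2)
  if (is.null(option_a) || is.null(option_b)) {
    canonical <- switch(as.character(experiment_id),
      "1" = list(a = el, b = ll, target = "EL"),
      "2" = list(a = ee, b = ll, target = "EE"),
      "3" = list(a = ee, b = el, target = "EE"))
    option_a <- canonical$a
    option_b <- canonical$b
    if (is.null(target_option)) target_option <- canonical$target
  }
  stopifnot(inherits(option_a, "option_spec"), inherits(option_b, "option_spec"))
  if (option_a$label == option_b$label)
    stop("the two options must carry distinct labels")
  if (option_a$shock_delay == option_b$shock_delay &&
      option_a$reward_delay == option_b$reward_delay)
    stop("the two options must differ in at least one delay")
  if (is.null(target_option)) target_option <- option_a$label
  if (!target_option %in% c(option_a$label, option_b$label))
    stop("target_option must be one of the two option labels")
  structure(
    list(experiment_id = as.integer(experiment_id),
         option_a = option_a, option_b = option_b,
         target_option = target_option),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  fmt <- function(o) sprintf("%s (shock %g s, reward %g s x %g pellets)",
                             o$label, o$shock_delay, o$reward_delay,
                             o$reward_magnitude)
  cat(sprintf("Experiment %d design\n  A: %s\n  B: %s\n  reported option: %s\n",
              x$experiment_id, fmt(x$option_a), fmt(x$option_b),
              x$target_option))
  invisible(x)
}

design_labels <- function(design)
  c(design$option_a$label, design$option_b$label)

trial_columns <- c("experiment_id", "subject_id", "session", "trial_index",
                   "trial_type", "offered", "chosen", "omission",
                   "side_of_target")

#' Construct and validate a trial table
#'
#' A trial table is the single interchange format of the pipeline: one row per
#' trial with the subject, session (1..n_sessions), trial index within the
#' session, trial type (`forced` with a single offered option, `free` with
#' both), the chosen option (`NA` on omission trials), an omission flag, and
#' the side (left/right) on which the reported option sat that session.
#'
#' Validation enforces: unique (subject, session, trial_index); option labels
#' drawn from the design; forced trials offer exactly one option while free
#' trials offer both (encoded `"A|B"`); omission implies no recorded choice,
#' and omissions occur only on free trials.
#'
#' @param df A data.frame with columns `experiment_id, subject_id, session,
#'   trial_index, trial_type, offered, chosen, omission, side_of_target`.
#' @param design The [experiment_design()] the trials were collected under.
#' @return `df`, validated, with class `trial_table` and the design attached
#'   as attribute `"design"`.
#' @export
trial_table <- function(df, design) {
  stopifnot(is.data.frame(df), inherits(design, "experiment_design"))
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols))
    stop("trial table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[trial_columns]
  df$experiment_id <- as.integer(df$experiment_id)
  df$subject_id <- as.character(df$subject_id)
  df$session <- as.integer(df$session)
  df$trial_index <- as.integer(df$trial_index)
  df$trial_type <- as.character(df$trial_type)
  df$offered <- as.character(df$offered)
  df$chosen <- as.character(df$chosen)
  df$chosen[!is.na(df$chosen) & df$chosen == ""] <- NA_character_
  df$omission <- as.logical(df$omission)
  df$side_of_target <- as.character(df$side_of_target)

  if (nrow(df)) {
    labels <- design_labels(design)
    if (anyNA(df$session) || anyNA(df$trial_index) ||
        any(df$session < 1L) || any(df$trial_index < 1L))
      stop("trial table integrity error: session and trial_index must be positive integers")
    key <- paste(df$subject_id, df$session, df$trial_index, sep = "\r")
    if (anyDuplicated(key))
      stop("trial table integrity error: duplicate (subject, session, trial_index)")
    if (!all(df$trial_type %in% c("forced", "free")))
      stop("trial table domain error: trial_type must be 'forced' or 'free'")
    offered_parts <- strsplit(df$offered, "|", fixed = TRUE)
    n_offered <- lengths(offered_parts)
    if (any(df$trial_type == "forced" & n_offered != 1L))
      stop("trial table integrity error: forced trials must offer exactly one option")
    if (any(df$trial_type == "free" & n_offered != 2L))
      stop("trial table integrity error: free trials must offer both options")
    if (!all(unlist(offered_parts) %in% labels))
      stop("trial table domain error: offered option label not in the design (",
           paste(labels, collapse = ", "), ")")
    if (!all(df$chosen[!is.na(df$chosen)] %in% labels))
      stop("trial table domain error: chosen option label not in the design")
    if (any(df$omission & !is.na(df$chosen)))
      stop("trial table integrity error: omission trials cannot record a choice")
    if (any(!df$omission & is.na(df$chosen)))
      stop("trial table integrity error: non-omission trials must record a choice")
    if (any(df$omission & df$trial_type == "forced"))
      stop("trial table integrity error: omissions can only occur on free trials")
    if (!all(df$side_of_target %in% c("left", "right")))
      stop("trial table domain error: side_of_target must be 'left' or 'right'")
  }
  structure(df, design = design, class = c("trial_table", "data.frame"))
}

#' @export
print.trial_table <- function(x, ...) {
  design <- attr(x, "design")
  cat(sprintf("Trial table: %d trials, %d subject(s), experiment %d (reported option %s)\n",
              nrow(x), length(unique(x$subject_id)),
              design$experiment_id, design$target_option))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a trial-level choice log from CSV
#'
#' The CSV dialect is comma-separated UTF-8 with one header row and columns
#' exactly `experiment_id, subject_id, session, trial_index, trial_type,
#' offered, chosen, omission, side_of_target`; booleans are written
#' `true`/`false` and an omitted choice is an empty field. Malformed files are
#' rejected with an informative error, never silently repaired.
#'
#' @param path Path to the CSV file.
#' @param design The [experiment_design()] to validate the log against.
#' @return A [trial_table()].
#' @seealso [write_trials()]
#' @export
load_trials <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                        check.names = FALSE)
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols))
    stop("trial table schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df)) {
    bad_bool <- !df$omission %in% c("true", "false")
    if (any(bad_bool))
      stop("trial table schema error: omission must be 'true' or 'false' (row ",
           which(bad_bool)[1], ")")
    df$omission <- df$omission == "true"
    df$chosen[df$chosen == ""] <- NA_character_
    suppressWarnings({
      df$experiment_id <- as.integer(df$experiment_id)
      df$session <- as.integer(df$session)
      df$trial_index <- as.integer(df$trial_index)
    })
  } else {
    df$omission <- logical(0)
  }
  trial_table(df, design)
}

#' Write a trial table to CSV
#'
#' Serialization is deterministic: fixed column order, `true`/`false`
#' booleans, empty field for an omitted choice. `load_trials()` on the result
#' reproduces the table exactly.
#'
#' @param table A [trial_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trials <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  out <- as.data.frame(table)
  out$omission <- ifelse(out$omission, "true", "false")
  out$chosen[is.na(out$chosen)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-subject choice fractions
#'
#' Reduces a trial table to the analysis's dependent variable: for each
#' subject, the percentage of valid free trials on which the reported
#' (target) option was chosen. Forced trials are never counted; omission
#' trials are excluded from both numerator and denominator. A subject with no
#' valid free trial gets an explicit `NA` fraction rather than a silent zero.
#'
#' @param table A [trial_table()].
#' @return A data.frame with columns `subject_id`, `n_free_valid`,
#'   `n_omissions`, `fraction_target` (percent).
#' @examples
#' design <- experiment_design(1)
#' tab <- generate_binomial_cohort(cohort_spec(n_subjects = 2, p_choice = 0.6,
#'                                             seed = 1), design)
#' choice_fractions(tab)
#' @export
choice_fractions <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  if (!nrow(table)) stop("empty trial table")
  design <- attr(table, "design")
  target <- design$target_option
  subjects <- unique(table$subject_id)
  free <- table$trial_type == "free"
  res <- lapply(subjects, function(s) {
    rows <- table$subject_id == s & free
    valid <- rows & !table$omission
    n_valid <- sum(valid)
    data.frame(
      subject_id = s,
      n_free_valid = n_valid,
      n_omissions = sum(rows & table$omission),
      fraction_target = if (n_valid == 0L) NA_real_ else
        100 * sum(table$chosen[valid] == target) / n_valid,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
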