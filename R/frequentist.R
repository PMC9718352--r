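#' One-sample t test against chance
#'
#' Two-tailed one-sample t test of per-subject choice percentages against the
#' 50\% chance level (or another reference), the primary significance test
#' for a group preference.
#'
#' @param values Per-subject percentages; `NA`s are dropped with a warning.
#' @param chance Reference value, default 50 (percent).
#' @return An object of class `ttest_result` with fields `t`, `df`, `p`,
#'   `mean`, `sem`, `n`, `chance`.
#' @examples
#' one_sample_t(c(55, 60, 50, 45, 65))
#' @export
one_sample_t <- function(values, chance = 50) {
  values <- as.numeric(values)
  if (anyNA(values)) {
    warning("dropping ", sum(is.na(values)), " missing value(s)")
    values <- values[!is.na(values)]
  }
  if (length(values) < 2) stop("need at least 2 subjects for a t test")
  if (stats::sd(values) == 0)
    stop("degenerate input: zero variance across subjects")
  tt <- stats::t.test(values, mu = chance, alternative = "two.sided")
  structure(
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean = mean(values),
         sem = stats::sd(values) / sqrt(length(values)),
         n = length(values), chance = chance),
    class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("One-sample t test vs %g: mean +/- SEM = %.2f +/- %.2f, t(%d) = %.3f, p = %.4g\n",
              x$chance, x$mean, x$sem, x$df, x$t, x$p))
  invisible(x)
}

#' Per-subject percentages by within-session or across-session blocks
#'
#' Partitions the valid free trials into the factorial cells used by the
#' learning analyses:
#' \describe{
#'   \item{`trial_block`}{first half vs second half of each session's free
#'     trials (trials 1-8 vs 9-16 in the standard task), crossed with
#'     session number -- learning within sessions.}
#'   \item{`session_block`}{first half vs second half of the sessions
#'     (sessions 1-5 vs 6-10), crossed with session order within the block --
#'     change over the experiment.}
#' }
#' Cell values are the percentage of target choices among the cell's valid
#' free trials; an empty cell yields an explicit `NA`.
#'
#' @param table A [trial_table()].
#' @param blocking `"trial_block"` or `"session_block"`.
#' @return A long data.frame with columns `subject_id`, `block`, `occasion`
#'   and `percent`, suitable for [rm_anova()]; the blocking mode is attached
#'   as attribute `"blocking"`.
#' @export
block_aggregate <- function(table, blocking = c("trial_block", "session_block")) {
  stopifnot(inherits(table, "trial_table"))
  blocking <- match.arg(blocking)
  design <- attr(table, "design")
  target <- design$target_option
  df <- as.data.frame(table)
  df <- df[df$trial_type == "free", ]
  # free-trial order within the session (1..n_free), independent of how many
  # forced trials preceded
  ord <- order(df$subject_id, df$session, df$trial_index)
  df <- df[ord, ]
  df$free_order <- stats::ave(df$trial_index,
                              df$subject_id, df$session,
                              FUN = function(x) rank(x))
  n_sessions <- max(df$session)
  if (blocking == "trial_block") {
    n_free <- max(df$free_order)
    half <- ceiling(n_free / 2)
    df$block <- ifelse(df$free_order <= half, 1L, 2L)
    df$occasion <- df$session
  } else {
    half <- ceiling(n_sessions / 2)
    df$block <- ifelse(df$session <= half, 1L, 2L)
    df$occasion <- ifelse(df$block == 1L, df$session, df$session - half)
  }
  valid <- !df$omission
  subjects <- unique(df$subject_id)
  grid <- expand.grid(subject_id = subjects,
                      block = sort(unique(df$block)),
                      occasion = sort(unique(df$occasion)),
                      stringsAsFactors = FALSE)
  grid$percent <- mapply(function(s, b, o) {
    cell <- valid & df$subject_id == s & df$block == b & df$occasion == o
    if (!any(cell)) return(NA_real_)
    100 * sum(df$chosen[cell] == target) / sum(cell)
  }, grid$subject_id, grid$block, grid$occasion)
  grid$block <- factor(grid$block)
  grid$occasion <- factor(grid$occasion)
  attr(grid, "blocking") <- blocking
  grid
}

# normalised Helmert contrasts: t(C) %*% C = I, columns orthogonal to 1
orthonormal_contrasts <- function(levels) {
  cm <- stats::contr.helmert(levels)
  cm %*% diag(1 / sqrt(colSums(cm^2)), ncol(cm))
}

# Greenhouse-Geisser epsilon and Mauchly's test for one within effect, from
# the subjects x cells matrix Y and the effect's orthonormal contrast M.
sphericity_stats <- function(Y, M) {
  d <- ncol(M)
  if (d < 2) return(list(epsilon = 1, W = NA_real_, p = NA_real_))
  Z <- Y %*% M
  S <- stats::cov(Z)
  tr <- sum(diag(S))
  epsilon <- tr^2 / (d * sum(S * S))
  W <- det(S) / (tr / d)^d
  # chi-square approximation with Mauchly's second-order correction term
  nd <- nrow(Y) - 1
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nd)
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
    (288 * (nd * d * rho)^2)
  z <- -nd * rho * log(max(W, .Machine$double.xmin))
  df <- d * (d + 1) / 2 - 1
  p1 <- stats::pchisq(z, df, lower.tail = FALSE)
  p2 <- stats::pchisq(z, df + 4, lower.tail = FALSE)
  list(epsilon = epsilon, W = W, p = p1 + w2 * (p2 - p1))
}

#' Two-way repeated-measures ANOVA with effect sizes
#'
#' Classical two-way within-subject decomposition (both factors within
#' subjects) fitted through [stats::aov()] with
#' `Error(subject/(A*B))` strata. Reports per effect the F ratio, degrees of
#' freedom, p value and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`). For effects with more than one
#' numerator degree of freedom, Mauchly's sphericity test is run on the
#' orthonormal-contrast covariance and, when it rejects at `alpha`, the
#' Greenhouse-Geisser correction is applied; both uncorrected and corrected
#' p values are always reported. Subjects with any missing cell are dropped
#' listwise with a warning (degrees of freedom shrink accordingly).
#'
#' @param cells Long data.frame of per-subject factorial percentages, e.g.
#'   from [block_aggregate()].
#' @param dv,within,subject Column names of the dependent variable, the two
#'   within-subject factors, and the subject identifier.
#' @param alpha Significance level of Mauchly's test gating the GG
#'   correction (default 0.05).
#' @return An object of class `rm_anova`: data.frame `effects` with columns
#'   `effect, df_num, df_den, ss, ss_error, F, p, eta_sq, gg_epsilon,
#'   mauchly_p, df_num_gg, df_den_gg, p_gg, sphericity_violated`, plus
#'   `ss_subjects`, `ss_total` and `n_subjects` for bookkeeping.
#' @examples
#' tab <- generate_binomial_cohort(cohort_spec(10, 0.6, seed = 3),
#'                                 experiment_design(1))
#' rm_anova(block_aggregate(tab, "trial_block"))
#' @export
rm_anova <- function(cells, dv = "percent", within = c("block", "occasion"),
                     subject = "subject_id", alpha = 0.05) {
  stopifnot(is.data.frame(cells), length(within) == 2,
            all(c(dv, within, subject) %in% names(cells)))
  d <- data.frame(y = as.numeric(cells[[dv]]),
                  A = factor(cells[[within[1]]]),
                  B = factor(cells[[within[2]]]),
                  id = factor(cells[[subject]]))
  a <- nlevels(d$A); b <- nlevels(d$B)
  if (a < 2 || b < 2) stop("each within-subject factor needs >= 2 levels")
  # listwise deletion of subjects with missing or incomplete cells
  complete <- tapply(d$y, d$id, function(y) length(y) == a * b && !anyNA(y))
  bad <- names(complete)[!complete]
  if (length(bad)) {
    warning("dropping ", length(bad),
            " subject(s) with incomplete cells: ",
            paste(utils::head(bad, 5), collapse = ", "))
    d <- d[!d$id %in% bad, ]
    d$id <- droplevels(d$id)
  }
  n <- nlevels(d$id)
  if (n < 2) stop("fewer than 2 complete subjects")

  fit <- stats::aov(y ~ A * B + Error(id / (A * B)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- match(effect, trimws(rownames(tab)))
    err <- match("Residuals", trimws(rownames(tab)))
    c(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
      ss_err = tab[err, "Sum Sq"], df_err = tab[err, "Df"])
  }
  specs <- list(A = c("id:A", "A"), B = c("id:B", "B"),
                `A:B` = c("id:A:B", "A:B"))
  names(specs) <- c(within[1], within[2],
                    paste(within[1], within[2], sep = ":"))

  # subjects x cells matrix (A-major ordering) for sphericity statistics
  d <- d[order(d$id, d$A, d$B), ]
  Y <- matrix(d$y, nrow = n, ncol = a * b, byrow = TRUE)
  CA <- orthonormal_contrasts(a); CB <- orthonormal_contrasts(b)
  ja <- matrix(1 / sqrt(a), a, 1); jb <- matrix(1 / sqrt(b), b, 1)
  contrasts <- list(kronecker(CA, jb), kronecker(ja, CB), kronecker(CA, CB))

  effects <- do.call(rbind, lapply(seq_along(specs), function(i) {
    v <- pull(specs[[i]][1], specs[[i]][2])
    Fval <- (v["ss"] / v["df"]) / (v["ss_err"] / v["df_err"])
    p <- stats::pf(Fval, v["df"], v["df_err"], lower.tail = FALSE)
    sph <- sphericity_stats(Y, contrasts[[i]])
    violated <- !is.na(sph$p) && sph$p < alpha
    df1g <- sph$epsilon * v["df"]; df2g <- sph$epsilon * v["df_err"]
    data.frame(
      effect = names(specs)[i],
      df_num = unname(v["df"]), df_den = unname(v["df_err"]),
      ss = unname(v["ss"]), ss_error = unname(v["ss_err"]),
      F = unname(Fval), p = unname(p),
      eta_sq = unname(v["ss"] / (v["ss"] + v["ss_err"])),
      gg_epsilon = sph$epsilon, mauchly_p = sph$p,
      df_num_gg = unname(df1g), df_den_gg = unname(df2g),
      p_gg = unname(stats::pf(Fval, df1g, df2g, lower.tail = FALSE)),
      sphericity_violated = violated,
      stringsAsFactors = FALSE)
  }))
  rownames(effects) <- effects$effect

  subj_tab <- sm[["Error: id"]][[1]]
  ss_subjects <- subj_tab[match("Residuals", trimws(rownames(subj_tab))),
                          "Sum Sq"]
  structure(
    list(effects = effects, ss_subjects = ss_subjects,
         ss_total = sum((d$y - mean(d$y))^2), n_subjects = n,
         alpha = alpha),
    class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (%d complete subjects)\n",
              x$n_subjects))
  for (i in seq_len(nrow(x$effects))) {
    e <- x$effects[i, ]
    if (isTRUE(e$sphericity_violated)) {
      cat(sprintf("  %s: F(%.3f, %.3f) = %.3f, p = %.4g (GG-corrected), eta2 = %.3f\n",
                  e$effect, e$df_num_gg, e$df_den_gg, e$F, e$p_gg, e$eta_sq))
    } else {
      cat(sprintf("  %s: F(%d, %d) = %.3f, p = %.4g, eta2 = %.3f\n",
                  e$effect, e$df_num, e$df_den, e$F, e$p, e$eta_sq))
    }
  }
  invisible(x)
}
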