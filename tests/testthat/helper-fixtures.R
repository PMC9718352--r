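# Small builders shared across test files. Everything is generated in code;
# no stored fixtures.

# hand-built table: one subject, one session, 6 forced + 16 free trials of
# which `n_omit` are omissions and `n_target` of the valid free trials go to
# the target option
fixture_one_subject <- function(design = experiment_design(1),
                                n_target = 7, n_omit = 2) {
  labels <- c(design$option_a$label, design$option_b$label)
  target <- design$target_option
  other <- setdiff(labels, target)
  n_free <- 16
  n_valid <- n_free - n_omit
  chosen_free <- c(rep(target, n_target), rep(other, n_valid - n_target),
                   rep(NA_character_, n_omit))
  omit <- c(rep(FALSE, n_valid), rep(TRUE, n_omit))
  df <- data.frame(
    experiment_id = design$experiment_id,
    subject_id = "r1",
    session = 1L,
    trial_index = 1:22,
    trial_type = c(rep("forced", 6), rep("free", 16)),
    offered = c(rep(labels, 3), rep(paste(labels, collapse = "|"), 16)),
    chosen = c(rep(labels, 3), chosen_free),
    omission = c(rep(FALSE, 6), omit),
    side_of_target = "left",
    stringsAsFactors = FALSE)
  trial_table(df, design)
}

# per-subject factorial percentages with every cell present
fixture_cells <- function(n_subj = 10, a = 2, b = 5, seed = 1, sd = 10) {
  set.seed(seed)
  cells <- expand.grid(subject_id = sprintf("s%02d", seq_len(n_subj)),
                       block = factor(seq_len(a)),
                       occasion = factor(seq_len(b)),
                       stringsAsFactors = FALSE)
  cells$percent <- round(stats::rnorm(nrow(cells), 50, sd), 4)
  cells
}

# brute-force classical two-way within-subject ANOVA from first principles
# (cell means and sums of squares), independent of aov()
brute_rm_anova <- function(cells) {
  y <- cells$percent
  A <- factor(cells$block); B <- factor(cells$occasion)
  id <- factor(cells$subject_id)
  n <- nlevels(id); a <- nlevels(A); b <- nlevels(B)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  mS <- tapply(y, id, mean)
  mSA <- tapply(y, list(id, A), mean)
  mSB <- tapply(y, list(id, B), mean)
  ss_A <- n * b * sum((mA - grand)^2)
  ss_B <- n * a * sum((mB - grand)^2)
  ss_S <- a * b * sum((mS - grand)^2)
  ss_AB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + grand)^2)
  ss_SA <- b * sum((sweep(sweep(mSA, 1, mS), 2, mA) + grand)^2)
  ss_SB <- a * sum((sweep(sweep(mSB, 1, mS), 2, mB) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_SAB <- ss_tot - ss_A - ss_B - ss_AB - ss_S - ss_SA - ss_SB
  list(
    A = list(ss = ss_A, ss_err = ss_SA, df = a - 1, df_err = (n - 1) * (a - 1)),
    B = list(ss = ss_B, ss_err = ss_SB, df = b - 1, df_err = (n - 1) * (b - 1)),
    AB = list(ss = ss_AB, ss_err = ss_SAB, df = (a - 1) * (b - 1),
              df_err = (n - 1) * (a - 1) * (b - 1)),
    ss_subjects = ss_S, ss_total = ss_tot)
}
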