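test_that("one-sample t test matches the textbook formula", {
  vals <- c(55, 60, 50, 45, 65)
  res <- one_sample_t(vals)
  m <- mean(vals); s <- sd(vals); n <- length(vals)
  expect_equal(res$t, (m - 50) / (s / sqrt(n)), tolerance = 1e-12)
  expect_equal(res$t, 1.4142, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)
  expect_equal(res$mean, 55)
  expect_equal(res$sem, s / sqrt(5))

  # null case
  null <- one_sample_t(c(48, 52, 50 + 1e-9, 50 - 1e-9))
  expect_lt(abs(null$t), 1e-6)

  # shift invariance: t unchanged when values and chance shift together
  res2 <- one_sample_t(vals + 17, chance = 67)
  expect_equal(res2$t, res$t, tolerance = 1e-10)

  expect_error(one_sample_t(55), "at least 2")
  expect_error(one_sample_t(c(50, 50, 50)), "zero variance")
  expect_warning(one_sample_t(c(55, 60, NA, 45)), "missing")
})

test_that("block aggregation splits free trials and sessions at the stated cuts", {
  design <- experiment_design(1)
  tab <- generate_binomial_cohort(cohort_spec(3, p_choice = 0.7, seed = 51),
                                  design)
  tb <- block_aggregate(tab, "trial_block")
  expect_setequal(levels(tb$block), c("1", "2"))
  expect_equal(nlevels(tb$occasion), 10)
  expect_equal(nrow(tb), 3 * 2 * 10)

  # hand tally for one subject/session cell: free trials are indices 7..22,
  # block 1 = free trials 1..8 (indices 7..14)
  s1 <- tab[tab$subject_id == "s01" & tab$session == 4 &
              tab$trial_type == "free" & !tab$omission, ]
  first8 <- s1[order(s1$trial_index), ][1:min(8, nrow(s1)), ]
  manual <- 100 * mean(first8$chosen == "EL")
  got <- tb$percent[tb$subject_id == "s01" & tb$block == "1" &
                      tb$occasion == "4"]
  expect_equal(got, manual)

  sb <- block_aggregate(tab, "session_block")
  expect_equal(nlevels(sb$occasion), 5)
  # session 8 belongs to block 2, occasion 3
  s8 <- tab[tab$subject_id == "s02" & tab$session == 8 &
              tab$trial_type == "free" & !tab$omission, ]
  expect_equal(sb$percent[sb$subject_id == "s02" & sb$block == "2" &
                            sb$occasion == "3"],
               100 * mean(s8$chosen == "EL"))

  # a uniform chooser fills every cell with 100
  all_t <- generate_binomial_cohort(cohort_spec(2, p_choice = 1, seed = 1),
                                    design)
  expect_true(all(block_aggregate(all_t, "trial_block")$percent == 100))
})

test_that("rm_anova agrees with brute-force sums of squares", {
  cells <- fixture_cells(n_subj = 12, a = 2, b = 5, seed = 10)
  res <- rm_anova(cells)
  oracle <- brute_rm_anova(cells)
  for (pair in list(c("block", "A"), c("occasion", "B"),
                    c("block:occasion", "AB"))) {
    mine <- res$effects[pair[1], ]
    ref <- oracle[[pair[2]]]
    expect_equal(mine$ss, ref$ss, tolerance = 1e-10)
    expect_equal(mine$ss_error, ref$ss_err, tolerance = 1e-10)
    expect_equal(mine$df_num, ref$df)
    expect_equal(mine$df_den, ref$df_err)
    f_ref <- (ref$ss / ref$df) / (ref$ss_err / ref$df_err)
    expect_equal(mine$F, f_ref, tolerance = 1e-10)
    expect_equal(mine$p, pf(f_ref, ref$df, ref$df_err, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(mine$eta_sq, ref$ss / (ref$ss + ref$ss_err),
                 tolerance = 1e-10)
  }
  # SS partition identity
  parts <- res$ss_subjects + sum(res$effects$ss) + sum(res$effects$ss_error)
  expect_lt(abs(res$ss_total - parts) / res$ss_total, 1e-8)
})

test_that("two-level within factor F equals the squared paired t", {
  cells <- fixture_cells(n_subj = 9, a = 2, b = 4, seed = 22)
  res <- rm_anova(cells)
  m1 <- tapply(cells$percent[cells$block == 1],
               cells$subject_id[cells$block == 1], mean)
  m2 <- tapply(cells$percent[cells$block == 2],
               cells$subject_id[cells$block == 2], mean)
  tt <- t.test(m1[sort(names(m1))], m2[sort(names(m2))], paired = TRUE)
  expect_equal(res$effects["block", "F"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res$effects["block", "p"], tt$p.value, tolerance = 1e-10)
})

test_that("rm_anova matches car's univariate tests and GG correction", {
  skip_if_not_installed("car")
  cells <- fixture_cells(n_subj = 11, a = 2, b = 5, seed = 31)
  res <- rm_anova(cells)
  cells2 <- cells[order(cells$subject_id, cells$block, cells$occasion), ]
  Y <- matrix(cells2$percent, nrow = 11, byrow = TRUE)
  idata <- expand.grid(occasion = factor(1:5), block = factor(1:2))
  idata <- idata[, c("block", "occasion")]
  av <- suppressWarnings(
    summary(car::Anova(lm(Y ~ 1), idata = idata,
                       idesign = ~ block * occasion, type = 3),
            multivariate = FALSE))
  ut <- av$univariate.tests
  expect_equal(res$effects["block", "F"], ut["block", "F value"],
               tolerance = 1e-8)
  expect_equal(res$effects["occasion", "F"], ut["occasion", "F value"],
               tolerance = 1e-8)
  expect_equal(res$effects["block:occasion", "F"],
               ut["block:occasion", "F value"], tolerance = 1e-8)
  adj <- av$pval.adjustments
  expect_equal(res$effects["occasion", "gg_epsilon"],
               unname(adj["occasion", "GG eps"]), tolerance = 1e-8)
  expect_equal(res$effects["occasion", "p_gg"],
               unname(adj["occasion", "Pr(>F[GG])"]), tolerance = 1e-8)
})

test_that("incomplete subjects are dropped listwise with fewer dfs", {
  cells <- fixture_cells(n_subj = 8, a = 2, b = 3, seed = 40)
  cells$percent[cells$subject_id == "s03" & cells$block == 1 &
                  cells$occasion == 2] <- NA
  expect_warning(res <- rm_anova(cells), "incomplete")
  expect_equal(res$n_subjects, 7)
  expect_equal(res$effects["block", "df_den"], 6)
  # identical cells across one factor's levels leave it no sum of squares
  flat <- fixture_cells(n_subj = 6, a = 2, b = 3, seed = 41)
  flat$percent[flat$block == 2] <- flat$percent[flat$block == 1]
  res2 <- rm_anova(flat)
  expect_lt(res2$effects["block", "ss"], 1e-20)
  expect_lt(res2$effects["block:occasion", "ss"], 1e-20)
})
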