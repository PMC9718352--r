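test_that("contingency schedules never hold a side longer than two sessions", {
  for (seed in 1:50) {
    sch <- contingency_schedule(10, seed = seed)
    runs <- rle(sch)$lengths
    expect_true(all(runs <= 2))
  }
  expect_identical(contingency_schedule(10, seed = 7),
                   contingency_schedule(10, seed = 7))
})

test_that("schedules are balanced across seeds", {
  set.seed(99)
  rates <- vapply(1:1000, function(i)
    mean(contingency_schedule(10) == "left"), numeric(1))
  expect_gt(mean(rates), 0.35)
  expect_lt(mean(rates), 0.65)
  expect_true(any(rates > 0) && any(rates < 1))
})

test_that("binomial cohorts have the task's session structure", {
  design <- experiment_design(1)
  spec <- cohort_spec(n_subjects = 5, p_choice = 0.6,
                      omission_rate = 0.05, seed = 12)
  tab <- generate_binomial_cohort(spec, design)
  expect_s3_class(tab, "trial_table")
  per_session <- table(tab$subject_id, tab$session)
  expect_true(all(per_session == 22))
  # forced trials: 3 per arm per session, always completed
  forced <- tab[tab$trial_type == "forced", ]
  counts <- table(forced$subject_id, forced$session, forced$offered)
  expect_true(all(counts == 3))
  expect_false(any(forced$omission))
  # omissions only on free trials, no recorded choice
  expect_true(all(tab$trial_type[tab$omission] == "free"))
  expect_true(all(is.na(tab$chosen[tab$omission])))
})

test_that("generation is reproducible and respects the choice rate", {
  design <- experiment_design(1)
  spec <- cohort_spec(n_subjects = 25, p_choice = 0.6, seed = 5)
  t1 <- generate_binomial_cohort(spec, design)
  t2 <- generate_binomial_cohort(spec, design)
  expect_identical(t1, t2)

  cf <- choice_fractions(t1)
  pooled <- sum(cf$fraction_target * cf$n_free_valid / 100) / sum(cf$n_free_valid)
  se <- sqrt(0.6 * 0.4 / sum(cf$n_free_valid))
  expect_lt(abs(pooled - 0.6), 3 * se)

  # degenerate rates
  all_in <- generate_binomial_cohort(cohort_spec(3, p_choice = 1, seed = 2),
                                     design)
  expect_true(all(choice_fractions(all_in)$fraction_target == 100))
  expect_equal(sum(generate_binomial_cohort(
    cohort_spec(3, p_choice = 0.5, omission_rate = 0, seed = 3),
    design)$omission), 0)
})

test_that("per-subject counts are consistent with the binomial model", {
  design <- experiment_design(1)
  tab <- generate_binomial_cohort(cohort_spec(100, p_choice = 0.6, seed = 17),
                                  design)
  cf <- choice_fractions(tab)
  k <- round(cf$fraction_target * cf$n_free_valid / 100)
  # chi-square GOF against Binomial(160, 0.6) over quantile bins
  qs <- qbinom(seq(0.1, 0.9, by = 0.1), 160, 0.6)
  breaks <- c(-1, unique(qs), 160)
  probs <- diff(pbinom(breaks, 160, 0.6))
  obs <- table(cut(k, breaks))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = probs / sum(probs)))
  expect_gt(gof$p.value, 0.01)
})

test_that("theory agents drive preferences in the predicted direction", {
  design1 <- experiment_design(1)
  spec <- cohort_spec(n_subjects = 25, p_choice = 0.5, seed = 41)

  # zero softmax temperature: indifference
  flat <- simulate_experiment(design1,
    theory_params("aversive_discounting", temperature = 0), spec)
  cf <- choice_fractions(flat)
  pooled <- sum(cf$fraction_target * cf$n_free_valid / 100) / sum(cf$n_free_valid)
  expect_lt(abs(pooled - 0.5), 3 * sqrt(0.25 / sum(cf$n_free_valid)))

  # aversive-discounting agent in exp 1 avoids the early shock (target EL)
  ad <- theory_params("aversive_discounting", k_reward = 0.05, k_shock = 0.1,
                      shock_cost = 3, temperature = 2)
  tab_ad <- simulate_experiment(design1, ad, spec)
  cf <- choice_fractions(tab_ad)
  pooled_ad <- sum(cf$fraction_target * cf$n_free_valid / 100) / sum(cf$n_free_valid)
  expect_lt(pooled_ad, 0.5 - 3 * sqrt(0.25 / sum(cf$n_free_valid)))

  # spillover agent in exp 3 disprefers EE (the target)
  sp <- theory_params("spillover", k_reward = 0, k_shock = 0,
                      spill_magnitude = 0.5, spill_decay = 0.2,
                      temperature = 2)
  expect_equal(unname(predict_preferences(sp)[["exp3"]]), "EL")
  tab_sp <- simulate_experiment(experiment_design(3), sp, spec)
  cf <- choice_fractions(tab_sp)
  pooled_sp <- sum(cf$fraction_target * cf$n_free_valid / 100) / sum(cf$n_free_valid)
  expect_lt(pooled_sp, 0.5 - 3 * sqrt(0.25 / sum(cf$n_free_valid)))
})
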