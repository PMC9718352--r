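test_that("beta shape parameters follow the mode-style reparameterisation", {
  expect_equal(unname(beta_shape_params(0.5, 2)), c(1, 1))
  expect_equal(unname(beta_shape_params(0.6, 102)), c(61, 41))
  expect_equal(unname(beta_shape_params(0.55, 22)), c(12, 10))
  # both shapes stay >= 1 across the support
  set.seed(19)
  for (i in 1:50) {
    ab <- beta_shape_params(runif(1, 0.01, 0.99), 2 + rexp(1, 0.01))
    expect_true(all(ab >= 1))
  }
  expect_error(beta_shape_params(0.5, 1.5), ">= 2")
  expect_error(beta_shape_params(0, 10), "strictly")
})

test_that("log posterior has the right support and conjugate structure", {
  pri <- prior_config()
  # zero subjects: prior-only value
  expect_equal(log_posterior(0.5, 10, numeric(0), numeric(0), numeric(0), pri),
               dbeta(0.5, 1, 1, log = TRUE) +
                 dgamma(8, 0.01, 0.01, log = TRUE))
  # boundary theta with successes is impossible
  expect_identical(log_posterior(0.5, 10, 0, 3, 10, pri), -Inf)
  expect_identical(log_posterior(0.5, 1.5, 0.5, 3, 10, pri), -Inf)
  # with mu, kappa held fixed the theta-profile equals the Beta(a+k, b+n-k)
  # log kernel up to a constant
  mu <- 0.55; kap <- 22; k <- 7; n <- 10
  ab <- beta_shape_params(mu, kap)
  thetas <- c(0.3, 0.45, 0.6, 0.8)
  lp <- vapply(thetas, function(th)
    log_posterior(mu, kap, th, k, n, pri), numeric(1))
  kernel <- dbeta(thetas, ab[1] + k, ab[2] + n - k, log = TRUE)
  expect_equal(diff(lp), diff(kernel), tolerance = 1e-12)
  expect_error(log_posterior(0.5, 10, c(0.5, 0.5), 3, 10, pri), "per subject")
})

test_that("the sampler is deterministic given a seed", {
  dat <- list(k = c(90, 100, 85), n = rep(160, 3))
  f1 <- bernbeta(dat, chains = 2, iter = 800, warmup = 200, seed = 9)
  f2 <- bernbeta(dat, chains = 2, iter = 800, warmup = 200, seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- bernbeta(dat, chains = 2, iter = 800, warmup = 200, seed = 10)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("every retained draw lies in the model's support", {
  set.seed(20)
  fit <- bernbeta(list(k = c(2, 150, 80), n = c(160, 160, 160)),
                  chains = 2, iter = 1500, warmup = 300, seed = 3)
  post <- as.matrix(fit)
  expect_true(all(post[, "mu"] > 0 & post[, "mu"] < 1))
  expect_true(all(post[, "kappa"] >= 2))
  th <- post[, grep("^theta", colnames(post))]
  expect_true(all(th > 0 & th < 1))
})

test_that("clamped hyperparameters give the conjugate Beta posterior", {
  fit <- bernbeta(list(k = 7, n = 10), chains = 2, iter = 12000, warmup = 2000,
                  seed = 3, fix_mu = 0.5, fix_kappa = 2)
  th <- as.matrix(fit)[, "theta[1]"]
  expect_gte(length(th), 20000)
  ks <- suppressWarnings(stats::ks.test(th, stats::pbeta, 8, 4))
  expect_lt(unname(ks$statistic), 0.02)
  expect_lt(abs(mean(th) - 8 / 12), 0.01)
})

test_that("the posterior mean recovers the generating rate", {
  tab <- generate_binomial_cohort(cohort_spec(25, p_choice = 0.6, seed = 23),
                                  experiment_design(1))
  fit <- bernbeta(tab, chains = 4, iter = 3000, warmup = 600, seed = 31)
  s <- summary(fit, check_convergence = FALSE)
  expect_lt(abs(s$mu_mean - 0.6), 0.02)
  expect_true(s$converged)
})

test_that("larger concentration shrinks subject estimates together", {
  dat <- list(k = c(60, 80, 100, 120), n = rep(160, 4))
  spread <- vapply(c(5, 200, 5000), function(kap) {
    fit <- bernbeta(dat, chains = 2, iter = 2000, warmup = 500, seed = 8,
                    fix_mu = 0.55, fix_kappa = kap)
    est <- coef(fit)
    stats::sd(est[grep("^theta", names(est))])
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("fit methods expose draws, coefficients and predictions", {
  tab <- generate_binomial_cohort(cohort_spec(6, p_choice = 0.6, seed = 29),
                                  experiment_design(2))
  fit <- bernbeta(tab, chains = 2, iter = 1500, warmup = 300, seed = 12)
  est <- coef(fit)
  expect_named(est, c("mu", "kappa", sprintf("theta[%d]", 1:6)))
  post <- as.matrix(fit)
  expect_equal(nrow(post), 2 * 1200)
  s <- summary(fit, check_convergence = FALSE)
  expect_true(all(s$params$hdi_lower < s$params$hdi_upper))
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_equal(dim(sim), c(50, 6))
  expect_true(all(sim >= 0 & sim <= 160))
  r <- residuals(fit)
  expect_length(r, 6)
  expect_true(all(abs(r) < 4))  # posterior-mean fit can't be wildly off
  # degenerate input
  expect_error(bernbeta(list(k = numeric(0), n = numeric(0))), "")
  expect_error(bernbeta(list(k = 0, n = 0)), "trial")
})
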