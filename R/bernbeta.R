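#' Prior configuration for the hierarchical Bernoulli-beta model
#'
#' The group-level mean gets an uninformed `Beta(1, 1)` prior; the
#' concentration gets a `Gamma(shape = 0.01, rate = 0.01)` prior (shape-rate
#' parameterisation, prior mean 1) placed on `kappa - kappa_floor` so that
#' every prior draw respects the floor `kappa >= 2` implied by the
#' mode-style beta reparameterisation (both beta shapes stay >= 1). The
#' near-flat gamma keeps the concentration conservative: per-subject
#' estimates are shrunk toward the group mean only when the data demand it.
#'
#' @param mu_shape1,mu_shape2 Beta prior shapes for the group mean.
#' @param kappa_shape,kappa_rate Gamma prior on `kappa - kappa_floor`.
#' @param kappa_floor Lower bound of the concentration; 2 in the standard
#'   model.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(mu_shape1 = 1, mu_shape2 = 1,
                         kappa_shape = 0.01, kappa_rate = 0.01,
                         kappa_floor = 2) {
  stopifnot(mu_shape1 > 0, mu_shape2 > 0, kappa_shape > 0, kappa_rate > 0,
            kappa_floor >= 0)
  structure(list(mu_shape1 = mu_shape1, mu_shape2 = mu_shape2,
                 kappa_shape = kappa_shape, kappa_rate = kappa_rate,
                 kappa_floor = kappa_floor),
            class = "prior_config")
}

#' Beta shape parameters from mean and concentration
#'
#' The hierarchical model draws each subject's choice probability from
#' `Beta(a, b)` with `a = mu * (kappa - 2) + 1` and
#' `b = (1 - mu) * (kappa - 2) + 1`. Both shapes are always >= 1, so the
#' subject-level prior is never U-shaped; at the floor `kappa = 2` it is
#' uniform.
#'
#' @param mu Group-level mean in (0, 1).
#' @param kappa Concentration, >= `floor`.
#' @param floor Concentration floor (default 2).
#' @return Numeric vector `c(a, b)`.
#' @examples
#' beta_shape_params(0.6, 102)  # c(61, 41)
#' @export
beta_shape_params <- function(mu, kappa, floor = 2) {
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must lie strictly in (0, 1)")
  if (any(kappa < floor)) stop("kappa must be >= ", floor)
  c(a = mu * (kappa - floor) + 1, b = (1 - mu) * (kappa - floor) + 1)
}

#' Unnormalised log posterior of the hierarchical model
#'
#' Sum of the Bernoulli log likelihoods
#' `k_s log(theta_s) + (n_s - k_s) log(1 - theta_s)`, the
#' `Beta(a, b)` log densities of each `theta_s` with shapes from
#' [beta_shape_params()], the gamma log prior of `kappa - floor` and the beta
#' log prior of `mu`. Returns `-Inf` outside the support. Used directly by
#' the sampler's acceptance ratio (up to the fixed transform Jacobians) and
#' available for external checks.
#'
#' @param mu,kappa Group-level parameters.
#' @param thetas Per-subject probabilities.
#' @param k,n Per-subject success and trial counts (same length as
#'   `thetas`).
#' @param priors A [prior_config()].
#' @return Log density (unnormalised).
#' @export
log_posterior <- function(mu, kappa, thetas, k, n, priors = prior_config()) {
  if (length(k) != length(n) || length(k) != length(thetas))
    stop("k, n and thetas must have one entry per subject")
  if (any(k < 0) || any(k > n)) stop("counts must satisfy 0 <= k <= n")
  if (mu <= 0 || mu >= 1 || kappa < priors$kappa_floor ||
      any(thetas <= 0) || any(thetas >= 1)) {
    # boundary cases with positive counts have zero likelihood
    return(-Inf)
  }
  ab <- beta_shape_params(mu, kappa, priors$kappa_floor)
  lik <- sum(k * log(thetas) + (n - k) * log1p(-thetas))
  lp_theta <- sum(stats::dbeta(thetas, ab[1], ab[2], log = TRUE))
  lp_kappa <- stats::dgamma(kappa - priors$kappa_floor, shape = priors$kappa_shape,
                            rate = priors$kappa_rate, log = TRUE)
  lp_mu <- stats::dbeta(mu, priors$mu_shape1, priors$mu_shape2, log = TRUE)
  lik + lp_theta + lp_kappa + lp_mu
}

# Normalise the many input shapes to per-subject (k, n) counts.
as_choice_counts <- function(data) {
  if (inherits(data, "trial_table")) {
    design <- attr(data, "design")
    target <- design$target_option
    free <- data$trial_type == "free" & !data$omission
    subjects <- unique(data$subject_id)
    k <- vapply(subjects, function(s)
      sum(free & data$subject_id == s & data$chosen == target), numeric(1))
    n <- vapply(subjects, function(s)
      sum(free & data$subject_id == s), numeric(1))
    if (any(n == 0)) {
      warning("dropping ", sum(n == 0), " subject(s) with no valid free trials")
      k <- k[n > 0]; subjects <- subjects[n > 0]; n <- n[n > 0]
    }
    return(list(k = unname(k), n = unname(n), subject_id = subjects))
  }
  if (is.matrix(data) && ncol(data) == 2)
    data <- list(k = data[, 1], n = data[, 2])
  if (is.data.frame(data)) {
    nm <- names(data)
    kcol <- intersect(c("k", "successes"), nm)[1]
    ncol_ <- intersect(c("n", "trials"), nm)[1]
    if (is.na(kcol) || is.na(ncol_))
      stop("data.frame input needs columns k/successes and n/trials")
    data <- list(k = data[[kcol]], n = data[[ncol_]],
                 subject_id = if ("subject_id" %in% nm) data$subject_id)
  }
  if (!is.list(data) || is.null(data$k) || is.null(data$n))
    stop("data must be a trial_table, a two-column matrix, a data.frame, ",
         "or a list with elements k and n")
  k <- as.numeric(data$k); n <- as.numeric(data$n)
  if (length(k) != length(n)) stop("k and n must have equal length")
  if (any(k < 0) || any(k > n)) stop("counts must satisfy 0 <= k <= n")
  if (all(n == 0)) stop("no subject has any trial")
  ids <- data$subject_id
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(k))
  list(k = k, n = n, subject_id = as.character(ids))
}

#' Fit the hierarchical Bernoulli-beta choice model
#'
#' Models each subject's free-trial choices of the reported option as
#' `k_s ~ Binomial(n_s, theta_s)` with
#' `theta_s ~ Beta(mu (kappa - 2) + 1, (1 - mu)(kappa - 2) + 1)`, an
#' uninformed `Beta(1, 1)` prior on the group mean `mu` and a
#' `Gamma(0.01, 0.01)` prior on the concentration above its floor
#' (see [prior_config()]). Sampling is by adaptive Metropolis-within-Gibbs on
#' the unconstrained scale (`logit mu`, `log(kappa - 2)`, `logit theta_s`),
#' with per-scalar proposal scales tuned toward 0.44 acceptance during warmup
#' only. Chains run sequentially from a single seeded RNG stream, so results
#' are exactly reproducible.
#'
#' @param data A [trial_table()], a two-column matrix `(successes, trials)`,
#'   a data.frame with columns `k`/`successes` and `n`/`trials`, or a list
#'   with elements `k` and `n`.
#' @param chains Number of chains (default 4).
#' @param iter Iterations per chain including warmup (default 5000).
#' @param warmup Warmup (adaptation) iterations per chain, discarded from
#'   summaries (default `iter / 5`).
#' @param priors A [prior_config()].
#' @param seed Integer seed for reproducibility.
#' @param fix_mu,fix_kappa Optional values at which to clamp the group
#'   parameters (degenerate point priors); used for conjugate checks, e.g.
#'   `fix_mu = 0.5, fix_kappa = 2` makes each `theta_s` posterior an exact
#'   `Beta(k + 1, n - k + 1)`.
#' @param adapt_batch Warmup batch length for proposal-scale adaptation.
#' @return An object of class `bernbeta` with elements `draws` (array
#'   iterations x chains x parameters, warmup included), `warmup`, `counts`,
#'   `priors`, `accept` (per-chain acceptance rates) and `call`. Methods:
#'   [summary.bernbeta()], [coef.bernbeta()], [plot.bernbeta()],
#'   [simulate.bernbeta()], [as.matrix.bernbeta()].
#' @examples
#' fit <- bernbeta(list(k = c(90, 102, 95), n = rep(160, 3)),
#'                 chains = 2, iter = 1500, seed = 1)
#' summary(fit)
#' @export
bernbeta <- function(data, chains = 4, iter = 5000, warmup = iter %/% 5,
                     priors = prior_config(), seed = NULL,
                     fix_mu = NULL, fix_kappa = NULL, adapt_batch = 50) {
  counts <- as_choice_counts(data)
  k <- counts$k; n <- counts$n
  stopifnot(chains >= 1, iter > warmup, warmup >= 0)
  if (!is.null(seed)) set.seed(seed)

  fm <- !is.null(fix_mu)
  fk <- !is.null(fix_kappa)
  if (fm && (fix_mu <= 0 || fix_mu >= 1)) stop("fix_mu must lie in (0, 1)")
  if (fk && fix_kappa < priors$kappa_floor)
    stop("fix_kappa must be >= ", priors$kappa_floor)

  pooled <- min(max(sum(k) / max(sum(n), 1), 0.02), 0.98)
  init_mu <- if (fm) fix_mu else pooled
  init_kappa <- if (fk) fix_kappa else priors$kappa_floor + 8
  init_theta <- pmin(pmax((k + 1) / (n + 2), 0.02), 0.98)

  S <- length(k)
  par_names <- c("mu", "kappa", sprintf("theta[%d]", seq_len(S)))
  draws <- array(NA_real_, dim = c(iter, chains, 2 + S),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 par_names))
  accept <- matrix(NA_real_, chains, 2 + S,
                   dimnames = list(NULL, par_names))
  for (ch in seq_len(chains)) {
    # overdispersed starts: jitter initial values per chain
    th0 <- pmin(pmax(init_theta + stats::rnorm(S, 0, 0.05), 0.02), 0.98)
    mu0 <- if (fm) fix_mu else
      min(max(init_mu + stats::rnorm(1, 0, 0.05), 0.02), 0.98)
    ka0 <- if (fk) fix_kappa else
      priors$kappa_floor + (init_kappa - priors$kappa_floor) *
        exp(stats::rnorm(1, 0, 0.5))
    res <- bernbeta_chain(k, n, as.integer(iter), as.integer(warmup),
                          priors$mu_shape1, priors$mu_shape2,
                          priors$kappa_shape, priors$kappa_rate,
                          priors$kappa_floor,
                          mu0, ka0, th0, fm, fk,
                          0.3, 0.8, 1.0, as.integer(adapt_batch))
    draws[, ch, ] <- res$draws
    accept[ch, ] <- res$accept
  }
  structure(
    list(draws = draws, warmup = as.integer(warmup), counts = counts,
         priors = priors, accept = accept,
         fixed = list(mu = fix_mu, kappa = fix_kappa),
         call = match.call()),
    class = "bernbeta")
}

#' Extract posterior draws as a matrix
#'
#' @param x A [bernbeta()] fit.
#' @param inc_warmup Keep warmup draws? Default `FALSE`.
#' @param ... Unused.
#' @return Matrix (chains stacked) with one column per parameter.
#' @export
as.matrix.bernbeta <- function(x, inc_warmup = FALSE, ...) {
  d <- x$draws
  if (!inc_warmup && x$warmup > 0)
    d <- d[-seq_len(x$warmup), , , drop = FALSE]
  out <- apply(d, 3, identity)  # (iter*chain) x par
  colnames(out) <- dimnames(x$draws)[[3]]
  out
}

# post-warmup draws of one parameter as an iterations x chains matrix
param_chains <- function(x, par) {
  d <- x$draws[, , par, drop = FALSE]
  if (x$warmup > 0) d <- d[-seq_len(x$warmup), , , drop = FALSE]
  matrix(d, nrow = dim(d)[1], ncol = dim(d)[2])
}

#' Summarise a hierarchical Bernoulli-beta fit
#'
#' Posterior means, 95\% highest density intervals, split-R-hat and effective
#' sample sizes for the group mean, the concentration and every subject-level
#' probability. A warning is raised when any R-hat is at or above `rhat_max`
#' (use `check_convergence = FALSE` to silence it).
#'
#' @param object A [bernbeta()] fit.
#' @param mass HDI mass (default 0.95).
#' @param rhat_max Convergence threshold (default 1.05).
#' @param check_convergence Warn on apparent non-convergence?
#' @param ... Unused.
#' @return A `summary.bernbeta` object: data.frame `params` with one row per
#'   parameter (`mean`, `hdi_lower`, `hdi_upper`, `rhat`, `ess`) plus the
#'   scalars `mu_mean`, `mu_hdi`, `converged`.
#' @export
summary.bernbeta <- function(object, mass = 0.95, rhat_max = 1.05,
                             check_convergence = TRUE, ...) {
  pars <- dimnames(object$draws)[[3]]
  fixed <- c(mu = !is.null(object$fixed$mu),
             kappa = !is.null(object$fixed$kappa))
  rows <- lapply(pars, function(p) {
    ch <- param_chains(object, p)
    is_fixed <- (p == "mu" && fixed["mu"]) || (p == "kappa" && fixed["kappa"])
    h <- hdi(as.numeric(ch), mass)
    data.frame(
      parameter = p, mean = mean(ch),
      hdi_lower = h[1], hdi_upper = h[2],
      rhat = if (is_fixed) NA_real_ else suppressWarnings(rhat(ch)),
      ess = if (is_fixed) NA_real_ else suppressWarnings(ess(ch)),
      stringsAsFactors = FALSE)
  })
  params <- do.call(rbind, rows)
  rownames(params) <- params$parameter
  worst <- suppressWarnings(max(params$rhat, na.rm = TRUE))
  converged <- is.finite(worst) && worst < rhat_max
  if (check_convergence && is.finite(worst) && !converged)
    warning(sprintf("possible non-convergence: max R-hat = %.3f >= %.2f",
                    worst, rhat_max))
  structure(
    list(params = params, mass = mass,
         mu_mean = params["mu", "mean"],
         mu_hdi = c(params["mu", "hdi_lower"], params["mu", "hdi_upper"]),
         converged = converged,
         n_subjects = length(object$counts$k),
         n_draws = (dim(object$draws)[1] - object$warmup) *
           dim(object$draws)[2]),
    class = "summary.bernbeta")
}

#' @export
print.summary.bernbeta <- function(x, digits = 3, ...) {
  cat(sprintf("Hierarchical Bernoulli-beta fit: %d subjects, %d post-warmup draws\n",
              x$n_subjects, x$n_draws))
  cat(sprintf("Group mean mu: %.3f, %d%% HDI (%.3f, %.3f)%s\n\n",
              x$mu_mean, round(100 * x$mass), x$mu_hdi[1], x$mu_hdi[2],
              if (x$converged) "" else "  [convergence suspect]"))
  print(format(x$params[, -1], digits = digits))
  invisible(x)
}

#' @export
print.bernbeta <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("bernbeta fit: %d subjects, %d chain(s) x %d iterations (%d warmup)\n",
              length(x$counts$k), d[2], d[1], x$warmup))
  mu <- as.numeric(param_chains(x, "mu"))
  if (is.null(x$fixed$mu))
    cat(sprintf("posterior mean of mu: %.3f\n", mean(mu)))
  invisible(x)
}

#' Posterior means of all parameters
#'
#' @param object A [bernbeta()] fit.
#' @param ... Unused.
#' @return Named numeric vector (`mu`, `kappa`, `theta[s]`).
#' @export
coef.bernbeta <- function(object, ...) {
  colMeans(as.matrix(object))
}

#' Plot the posterior of the group mean
#'
#' Kernel density of the post-warmup draws of `mu` with vertical lines at the
#' HDI bounds and at chance (0.5).
#'
#' @param x A [bernbeta()] fit.
#' @param mass HDI mass.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the HDI.
#' @export
plot.bernbeta <- function(x, mass = 0.95, ...) {
  mu <- as.numeric(param_chains(x, "mu"))
  h <- hdi(mu, mass)
  dens <- stats::density(mu)
  graphics::plot(dens, main = "Posterior of the group-level choice probability",
                 xlab = expression(mu[theta]), ...)
  graphics::abline(v = h, col = "grey40", lty = 2)
  graphics::abline(v = 0.5, col = "grey70")
  invisible(h)
}

#' Posterior predictive choice counts
#'
#' Draws replicated per-subject success counts: for each replicate a
#' posterior draw `theta_s` is selected and `k_s* ~ Binomial(n_s, theta_s)`
#' generated.
#'
#' @param object A [bernbeta()] fit.
#' @param nsim Number of replicated datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Matrix `nsim` x subjects of simulated success counts.
#' @export
simulate.bernbeta <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  post <- as.matrix(object)
  theta_cols <- grep("^theta\\[", colnames(post))
  idx <- sample.int(nrow(post), nsim, replace = TRUE)
  n <- object$counts$n
  out <- t(vapply(idx, function(i)
    stats::rbinom(length(n), size = n, prob = post[i, theta_cols]),
    numeric(length(n))))
  colnames(out) <- object$counts$subject_id
  out
}

#' Residuals of a hierarchical Bernoulli-beta fit
#'
#' Pearson residuals of the observed per-subject success counts against the
#' posterior-mean subject probabilities:
#' `(k - n * theta_hat) / sqrt(n * theta_hat * (1 - theta_hat))`.
#'
#' @param object A [bernbeta()] fit.
#' @param ... Unused.
#' @return Named numeric vector, one residual per subject.
#' @export
residuals.bernbeta <- function(object, ...) {
  est <- coef(object)
  th <- est[grep("^theta\\[", names(est))]
  k <- object$counts$k; n <- object$counts$n
  r <- (k - n * th) / sqrt(n * th * (1 - th))
  names(r) <- object$counts$subject_id
  r
}
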