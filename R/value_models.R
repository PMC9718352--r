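#' Hyperbolic temporal discount factor
#'
#' `1 / (1 + k * t)`: the standard hyperbolic decline of an outcome's
#' subjective value with the delay until it occurs, applied here to both
#' rewards and (as aversive discounting) shocks.
#'
#' @param t Delay in seconds (>= 0); vectorised.
#' @param k Discount rate in 1/s (>= 0).
#' @return Discount factor in (0, 1]; 1 at `t = 0` or `k = 0`.
#' @examples
#' hyperbolic_discount(20, 0.1)  # 1/3
#' @export
hyperbolic_discount <- function(t, k) {
  if (any(t < 0)) stop("delay t must be non-negative")
  if (any(k < 0)) stop("discount rate k must be non-negative")
  1 / (1 + k * t)
}

theory_names <- c("aversive_discounting", "utility_from_anticipation",
                  "spillover")

#' Parameters of a decision theory
#'
#' Bundles the parameterisation of one of three competing accounts of choice
#' between differently timed shocks and rewards:
#' \describe{
#'   \item{`aversive_discounting`}{both the reward's value and the shock's
#'     negative value decline hyperbolically with their delays; a later shock
#'     is less aversive.}
#'   \item{`utility_from_anticipation`}{aversive discounting plus dread:
#'     disutility accrued while waiting for the shock, growing with the
#'     entry-to-shock delay, so earlier shocks are preferred ("get it over
#'     with").}
#'   \item{`spillover`}{a shock devalues a temporally proximate subsequent
#'     reward; the devaluation decays exponentially with the shock-to-reward
#'     interval.}
#' }
#' Utilities are in arbitrary "utils"; only differences matter through the
#' softmax choice rule.
#'
#' @param theory One of `"aversive_discounting"`,
#'   `"utility_from_anticipation"`, `"spillover"`.
#' @param k_reward,k_shock Hyperbolic discount rates (1/s) for reward value
#'   and shock disutility.
#' @param reward_value Utils per delivered reward (per option, not per
#'   pellet).
#' @param shock_cost Positive magnitude of the shock's disutility in utils.
#' @param dread_coeff Utils of anticipatory disutility per unit shock cost
#'   and per second of entry-to-shock delay (anticipation theory only).
#' @param spill_magnitude Peak fraction of reward value destroyed by an
#'   immediately preceding shock, in `[0, 1]` (spillover theory only).
#' @param spill_decay Exponential decay rate (1/s) of the spill-over effect
#'   with the shock-to-reward interval.
#' @param temperature Softmax inverse-noise (1/utils); 0 gives random choice.
#' @return An object of class `theory_params`.
#' @export
theory_params <- function(theory = theory_names,
                          k_reward = 0.05, k_shock = 0.1,
                          reward_value = 3, shock_cost = 1,
                          dread_coeff = 0.2,
                          spill_magnitude = 0.5, spill_decay = 0.2,
                          temperature = 1) {
  theory <- match.arg(theory)
  if (k_reward < 0 || k_shock < 0 || spill_decay < 0)
    stop("rates must be non-negative")
  if (spill_magnitude < 0 || spill_magnitude > 1)
    stop("spill_magnitude must lie in [0, 1]")
  if (temperature < 0) stop("temperature must be non-negative")
  if (dread_coeff < 0) stop("dread_coeff must be non-negative")
  structure(
    list(theory = theory, k_reward = k_reward, k_shock = k_shock,
         reward_value = reward_value, shock_cost = shock_cost,
         dread_coeff = dread_coeff, spill_magnitude = spill_magnitude,
         spill_decay = spill_decay, temperature = temperature),
    class = "theory_params")
}

#' Utility of one option under a decision theory
#'
#' With `R = reward_value`, `S = shock_cost`, `d(t, k) = 1/(1 + k t)`,
#' entry-to-reward delay `t_r` and entry-to-shock delay `t_s`:
#' \describe{
#'   \item{aversive discounting}{`U = R d(t_r, k_reward) - S d(t_s, k_shock)`}
#'   \item{utility from anticipation}{the above `- dread_coeff * S * t_s`}
#'   \item{spillover}{`U = R d(t_r, k_reward) *
#'     (1 - spill_magnitude * exp(-spill_decay (t_r - t_s))) -
#'     S d(t_s, k_shock)`; requires the shock to precede the reward, as in
#'     all standard designs.}
#' }
#' An option without a shock (`shock_present = FALSE`) contributes no shock,
#' dread or spill-over term. Setting `dread_coeff = 0` or
#' `spill_magnitude = 0` recovers aversive discounting exactly.
#'
#' @param opt An [option_spec()].
#' @param params A [theory_params()].
#' @return Utility in utils.
#' @export
option_utility <- function(opt, params) {
  stopifnot(inherits(opt, "option_spec"), inherits(params, "theory_params"))
  r_term <- params$reward_value *
    hyperbolic_discount(opt$reward_delay, params$k_reward)
  if (!opt$shock_present) return(r_term)
  t_s <- opt$shock_delay
  t_r <- opt$reward_delay
  s_term <- params$shock_cost * hyperbolic_discount(t_s, params$k_shock)
  switch(params$theory,
    aversive_discounting = r_term - s_term,
    utility_from_anticipation =
      r_term - s_term - params$dread_coeff * params$shock_cost * t_s,
    spillover = {
      if (t_r < t_s)
        stop("spillover utility requires the shock to precede the reward")
      r_term * (1 - params$spill_magnitude *
                  exp(-params$spill_decay * (t_r - t_s))) - s_term
    })
}

#' Softmax probability of choosing option A
#'
#' `p = 1 / (1 + exp(-temperature * (u_a - u_b)))`. Saturates without
#' overflow; `temperature = 0` yields indifference (0.5).
#'
#' @param u_a,u_b Utilities of the two options (utils).
#' @param temperature Inverse-noise (1/utils, >= 0).
#' @return Probability in (0, 1) of choosing A (degenerate 0/1 only in the
#'   infinite-temperature limit).
#' @examples
#' choice_probability(1, 0, log(3))  # 0.75
#' @export
choice_probability <- function(u_a, u_b, temperature) {
  if (any(temperature < 0)) stop("temperature must be non-negative")
  stats::plogis(temperature * (u_a - u_b))
}

#' Predicted preference of a theory in each experiment
#'
#' Evaluates [option_utility()] for both arms of each design and returns the
#' label of the higher-utility option, or `"indifferent"` when the utilities
#' tie within `tol`.
#'
#' @param params A [theory_params()].
#' @param designs A list of [experiment_design()] objects (default: the three
#'   canonical designs).
#' @param tol Absolute utility difference below which the theory makes no
#'   prediction (default 1e-9 utils).
#' @return Named character vector, one entry per design (names
#'   `"exp<experiment_id>"`).
#' @examples
#' predict_preferences(theory_params("utility_from_anticipation"))
#' @export
predict_preferences <- function(params, designs = lapply(1:3, experiment_design),
                                tol = 1e-9) {
  stopifnot(inherits(params, "theory_params"))
  out <- vapply(designs, function(d) {
    u_a <- option_utility(d$option_a, params)
    u_b <- option_utility(d$option_b, params)
    if (abs(u_a - u_b) < tol) "indifferent"
    else if (u_a > u_b) d$option_a$label else d$option_b$label
  }, character(1))
  names(out) <- vapply(designs, function(d)
    paste0("exp", d$experiment_id), character(1))
  out
}
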