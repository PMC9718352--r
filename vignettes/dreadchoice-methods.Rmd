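---
title: "Models and methods behind dreadchoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dreadchoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreadchoice)
```

## The task and the question

dreadchoice analyses two-alternative T-maze experiments in which rats choose
between arms that deliver both an electric shock and a food reward at
different delays after arm entry. The early/late delays are 1 s or 20 s for
the shock and 2 s or 21 s for the reward, giving three option types: EL
(early shock, late reward), LL (late shock, late reward) and EE (early
shock, early reward). Three designs pit these against each other:

* **Experiment 1** (EL vs LL): identical reward timing, different shock
  timing.
* **Experiment 2** (EE vs LL): different shock timing, but a constant 1-s
  shock-to-reward interval in both arms.
* **Experiment 3** (EE vs EL): identical shock timing, different reward
  timing.

Subjects run 10 sessions of 6 forced trials (3 per arm, ensuring both
contingencies are sampled) followed by 16 free trials. Which arm carries
which contingency is pseudo-randomised per session, with a forced reversal
whenever a side would persist beyond two consecutive sessions, so the mapping
must be re-learned each day. Trials on which the animal leaves the arm before
the shock are omissions and carry no choice. The dependent variable is each
subject's percentage of valid free trials on which it chose the reported
option (EL in experiment 1, EE in experiments 2 and 3).

## Three decision theories

The package formalises three competing accounts as utility functions over the
delay structure (`option_utility()`), with `R` the reward value, `S` the
shock cost, and `d(t, k) = 1/(1 + kt)` the hyperbolic discount factor:

* **Aversive discounting**: `U = R d(t_r, k_reward) - S d(t_s, k_shock)`.
  A later shock is discounted, hence less aversive: LL is predicted in
  experiment 1.
* **Utility from anticipation**: the same minus a dread term
  `dread_coeff * S * t_s` that accrues while waiting for the shock, so
  earlier shocks are preferred: EL in experiment 1, EE in experiment 2.
* **Spill-over devaluation**: the shock devalues a temporally proximate
  subsequent reward,
  `U = R d(t_r, k_reward) (1 - m e^{-lambda (t_r - t_s)}) - S d(t_s, k_shock)`.

No equations for these theories exist in the behavioural literature at this
level of specificity; the functional forms above are this package's design
choices, selected as the simplest monotone forms consistent with the verbal
theories (hyperbolic decay for both outcome values, dread linear in the
anticipation period, spill-over decaying exponentially in the
shock-to-reward interval). They are deliberately modular: each reduces
exactly to aversive discounting when its extra coefficient is zero, which the
test suite verifies as a nesting property.

A softmax rule `p = 1/(1 + exp(-temperature (u_A - u_B)))` converts utility
differences into choice probabilities for simulated agents; ties within
`1e-9` utils are reported as "indifferent" by `predict_preferences()`.

The documented parameter region for the spill-over pattern uses
`k_reward = k_shock = 0` with `spill_magnitude = 0.5`,
`spill_decay = 0.2 /s`. Shutting off both discounting channels isolates the
spill-over mechanism, which is the regime in which the theory predicts the
observed pattern — EL preferred in experiment 1, indifference in experiment 2
(equal shock-to-reward intervals), and the late reward preferred in
experiment 3. With nonzero reward discounting the exp-2 indifference breaks
down, which is exactly the competition between mechanisms the theory
envisages; the test suite pins the pure regime.

```{r theories}
sp <- theory_params("spillover", k_reward = 0, k_shock = 0,
                    spill_magnitude = 0.5, spill_decay = 0.2)
predict_preferences(sp)
```

## The hierarchical Bernoulli–beta model

Free-trial decisions are modelled as subject-level Bernoulli draws with a
group-level beta population:

$$k_s \sim \mathrm{Binomial}(n_s, \theta_s), \qquad
\theta_s \sim \mathrm{Beta}\!\big(\mu(\kappa - 2) + 1,\; (1 - \mu)(\kappa - 2) + 1\big),$$

with an uninformed $\mathrm{Beta}(1, 1)$ prior on the group mean $\mu$ and a
$\mathrm{Gamma}(0.01, 0.01)$ prior (shape–rate) on $\kappa - 2$. The
reparameterisation keeps both beta shapes at or above 1 for every admissible
$(\mu, \kappa)$, so the subject-level prior is never U-shaped, and the floor
$\kappa \ge 2$ is respected by construction because the gamma prior is placed
on the *excess* concentration. The near-flat gamma makes $\kappa$
conservative: subjects are shrunk toward the group mean only when the data
support it.

`bernbeta()` samples this posterior with an adaptive Metropolis-within-Gibbs
sampler written for this package (C++ inner loop): Gaussian random-walk
proposals on $\mathrm{logit}\,\mu$, $\log(\kappa - 2)$ and
$\mathrm{logit}\,\theta_s$, each scalar's proposal scale adapted in batches
of 50 toward 0.44 acceptance during warmup only, then frozen so the retained
chain is a valid Markov chain. Chains run sequentially from one seeded RNG
stream; identical configuration and seed reproduce draws exactly.

Correctness is established two independent ways in the test suite:

* **Conjugate oracle** — with $\mu$ and $\kappa$ clamped (`fix_mu`,
  `fix_kappa`), each $\theta_s$ posterior is analytically
  $\mathrm{Beta}(a + k_s, b + n_s - k_s)$; the sampled distribution matches
  with Kolmogorov–Smirnov distance below 0.02 at 20,000+ draws.
* **Parameter recovery** — cohorts generated at known rates are recovered
  within 0.02 at the experimental group sizes.

During development the full $(\mu, \kappa)$ marginal was additionally checked
against 2-D quadrature on the $\theta$-marginalised beta-binomial posterior;
the MCMC means and intervals agree to about three decimals.

### Summaries and diagnostics

`summary()` reports posterior means, 95% highest density intervals, split
R-hat and autocorrelation-based effective sample sizes per parameter. The
HDI (`hdi()`) is the narrowest sorted window holding the requested mass; on
multimodal draw sets it still returns the single shortest window, which can
bridge modes. R-hat (`rhat()`) is the classic Gelman–Rubin variance-ratio
statistic on split chains, so a single trending chain is detected. ESS
(`ess()`) uses the combined-chain autocorrelation with Geyer's initial
monotone positive-sequence truncation, capped at the number of draws. The
default convergence expectation is R-hat < 1.05; pipeline functions flag
rather than retry non-convergent fits, keeping runs reproducible.

Default MCMC settings (4 chains × 5,000 iterations, 1,000 warmup) give
effective sample sizes around 1,000 for $\mu$ on experiment-sized data and
run in well under a second; the historical reference configuration
(12 × 15,000, 5,000 warmup) is available by argument.

## The synthetic generator

`generate_binomial_cohort()` emulates the task's generative structure:
per-subject sessions of 6 forced + 16 free trials, the contingency schedule
with forced reversals, omissions at the observed per-experiment rates
(0.80%, 0.02%, 0.13%), and free-trial choices as independent Bernoulli draws
of the target option. `simulate_experiment()` replaces the fixed rate with a
theory agent's softmax probability. Default cohort sizes are the
experimental group sizes (25, 20, 21).

What the generator deliberately does **not** reproduce: within-session
learning or relearning after contingency reversals, side biases, sequential
dependence between trials, and between-subject heterogeneity in the
fixed-rate mode (every subject shares `p_choice`). Passing tests on this
generator therefore validate the estimation machinery under the analysis's
own assumptions — they do not show that real rats satisfy those assumptions.

The quantitative theory-prediction simulation
(`run_simulated_predictions()`) generates, for each cell of the prediction
table, a cohort expressing the predicted preference at rate 0.6 — the
weakest preference considered clearly away from chance — and fits the
hierarchical model. The published figure for this simulation plots, in each
panel, the fraction of the design's second (non-reported) column, so cells
whose predicted option is the reported one appear centred near 0.4; the
generator parameterises the plotted rate directly (`p_axis`), which
sidesteps the axis ambiguity while reproducing every printed interval.

## Frequentist battery

`one_sample_t()` is the two-tailed one-sample t test of per-subject
percentages against the 50% chance level. `block_aggregate()` builds the two
factorial layouts of the learning analyses: first vs second half of each
session's free trials crossed with session, and first vs second half of the
sessions crossed with session order within the block. `rm_anova()` fits the
classical two-way within-subject decomposition through `aov()` error strata
and reports partial $\eta^2 = SS_{effect}/(SS_{effect} + SS_{error})$;
for effects with two or more numerator degrees of freedom it computes
Mauchly's sphericity test (with the second-order chi-square correction, as
in base R) and applies the Greenhouse–Geisser correction when Mauchly
rejects at $\alpha = 0.05$, always reporting both corrected and uncorrected
p values. Subjects with any missing cell are removed listwise with a
warning — the published experiment-1 trial-block ANOVA has error df 23 from
n = 25, consistent with exactly this kind of deletion. The implementation is
validated against brute-force sums-of-squares formulas (to 1e-10), against
the squared-paired-t identity for two-level factors, and cross-checked
against an independent general-purpose ANOVA implementation.

## Numerical and design choices

* **Sampler initial values** are jittered per chain around the pooled rate
  (overdispersed starts), with proposal scales 0.3 / 0.8 / 1.0 for
  $\mu$ / $\kappa$ / $\theta$ before adaptation.
* **Degenerate inputs**: subjects with zero valid free trials are dropped
  from fits with a warning and flagged `NA` in choice fractions; all-zero
  cohorts are an input error; constant chains make R-hat `NA` and ESS 0,
  with warnings.
* **Tie-breaking**: theory predictions declare indifference below
  `1e-9` utils; HDI windows of equal width resolve to the first (lowest)
  window.
* **Problem sizes**: the suite's simulation studies use 25-subject × 160
  free-trial cohorts (the experiment-1 scale); the interval-calibration
  study uses 200 replicates with 2 chains × 2,500 iterations per replicate,
  a scale at which the Monte-Carlo error of a coverage proportion is about
  1.5 percentage points.

## Known limitations

* **Conservative group-level intervals under homogeneous cohorts.** When
  every simulated subject shares one true rate, the fitted $\kappa$ stays
  finite (the near-flat gamma prior concentrates mass at small excess
  concentration), so the posterior for $\mu$ budgets for between-subject
  spread that such cohorts do not have. The 95% HDI then over-covers the
  shared rate — about 99% coverage in the 200-replicate study — and is
  wider (≈0.041 at the 25 × 160 scale) than a pure pooled-binomial interval
  (≈0.031). This is a property of the exact posterior, verified by
  quadrature, not of the sampler. On real data, where subjects genuinely
  differ, the same prior is what makes the interval honest.
* The theories are evaluated at fixed, documented parameter points; the
  package intentionally does not fit theory parameters to choice data.
* The generator's omissions are independent coin flips; real omissions
  likely cluster in early sessions and aversive arms.
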