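Package: dreadchoice
Title: Hierarchical Bayesian Analysis of Intertemporal Shock-Reward Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative T-maze choice experiments in
    which animals trade off differently timed electric shocks and food rewards.
    Provides a hierarchical Bernoulli-beta model of per-subject choice
    probabilities fitted by an adaptive Metropolis-within-Gibbs sampler with
    highest-density-interval summaries and convergence diagnostics (split
    R-hat, effective sample size); utility models for three competing decision
    theories (aversive discounting, utility from anticipation, and spill-over
    devaluation of rewards by temporally proximate shocks) with a softmax
    choice rule; a synthetic trial-level data generator emulating the task's
    session structure, pseudo-randomised arm contingencies and omissions; and
    the matching frequentist test battery (one-sample t tests against chance,
    two-way repeated-measures ANOVA with Greenhouse-Geisser correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
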