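---
title: "Bootstrap mediation for stepped-wedge trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap mediation for stepped-wedge trials: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a stepped-wedge cluster randomized trial, every cluster starts in the
control condition and crosses over to the intervention at a randomized,
staggered time. The design emulated here has 6 health-care clusters
(81/48/60/75/57/26 participants, 347 in total) randomized to 3 sequences that
cross over after 8, 16 or 24 weeks, with questionnaire assessments every
8 weeks for 5 waves. The scientific question is *mechanistic*: does a
web-based stress-management intervention reduce perceived stress (PSS-10)
*through* intermediate psychological processes — resilience (CD-RISC),
mindfulness facets (FFMQ-15), compassion (SOCS) and experiential avoidance
(AAQ-II)?

`swmediate` implements the full analysis pipeline: a long-format panel data
model, paired random-intercept linear mixed models, product-of-coefficients
mediation with cluster-stratified bootstrap inference, multivariate and
sensitivity variants, time-lagged mediator models, and a synthetic trial
generator so that every stage is testable without access to trial data.

## The mediation model

Two linear mixed models with a participant random intercept are fitted on the
post-baseline waves (2 to 5):

* **Model A (a-path):** `mediator ~ treatment + covariates + baseline outcome
  + (1 | participant)`
* **Model B (b-path and direct effect):** `outcome ~ mediator + treatment +
  covariates + baseline outcome + (1 | participant)`

The covariate set is cluster, gender, profession, age, contract type and
trainee status, plus the baseline (wave-1) level of the outcome. The indirect
effect is the product of coefficients `a * b`; the direct effect `c'` is the
treatment coefficient of model B.

Inference for the indirect effect uses a nonparametric bootstrap (1000
iterations by default). Each iteration resamples *participants* — entire
trajectories — with replacement, stratified by cluster so that cluster sizes
are preserved, refits both models, and records `a * b`. The 95% CI is the
2.5th/97.5th percentile of the bootstrap distribution and the p-value is the
two-sided sign-crossing proportion
`min(1, 2 * min(P(draw <= 0), P(draw >= 0)))`; the literal one-sided
proportion is kept alongside (`p_one_sided`).

```{r}
library(swmediate)
panel <- attach_baseline(generate_trial(sim_config(seed = 42)), "pss")
res <- bootstrap_mediation(panel, model_spec("pss", "cd_risc"),
                           n_boot = 1000, seed = 42)
res
```

The multivariate variant fits one a-model per mediator and a single joint
outcome model containing all mediators; per-mediator indirect effects are
computed inside the *same* resample each iteration, so the decomposition is
internally consistent. Two sensitivity models restrict the mediator set:
S1 keeps the mediators with univariate bootstrap p < .05; S2 keeps one
mediator per construct family (resilience / mindfulness / compassion /
acceptance), the most significant member, ties broken by larger absolute
indirect effect and then by name.

## Design choices that were genuinely open

* **Resampling unit.** Resampling rows would break both the within-participant
  correlation that the random intercept models and the cluster adjustment, so
  the resampling unit is the participant trajectory, stratified by cluster.
  Row-level resampling is available behind `resample_unit = "row"` for
  comparison; with singleton groups the random intercept is unidentified and
  that variant collapses to OLS, which is exactly the structure-breaking
  behaviour the flag is meant to expose.
* **Analysis waves.** Models are fitted on waves 2–5 with the wave-1 outcome
  as a covariate. Adjusting for baseline while also modelling wave 1 as a
  response would use the same measurement on both sides of the model.
* **Bootstrap p-value.** "Crossed zero" is operationalized as the two-sided
  sign proportion above; values below the bootstrap resolution `2/n_boot` are
  rendered as a bound (e.g. `<0.002`).
* **Percentile convention.** Linear interpolation between order statistics
  (`quantile` type 7), switchable to nearest-rank (type 1).
* **Treatment coding.** Exposure is "once crossed, always treated": later
  waves follow program completion and no washout is modelled. A
  `"current"` coding (1 only during the 8-week program window) is available.
* **Non-convergence inside the bootstrap.** A failed iteration is redrawn up
  to 3 times, then dropped; `n_boot_used` is reported and the run aborts if
  fewer than 95% of requested iterations survive.
* **Estimation criterion.** REML by default, ML behind a flag; single-fit
  p-values use the Wald normal approximation, since headline inference is
  bootstrap-based.

## The mixed-model engine

Every mediation model has a single random intercept, and the bootstrap refits
two such models per iteration. For this case the package uses its own
profiled-REML fitter: for a variance ratio `theta = var_group / var_resid`
the GLS estimate is OLS on quasi-demeaned data
`y - lambda_g * ybar_g`, `lambda_g = 1 - 1/sqrt(1 + theta * n_g)`, and the
REML deviance is profiled down to a one-dimensional search over `log(theta)`
(`optimize`, with an explicit check of the `theta = 0` boundary). This agrees
with `lme4::lmer` REML fits to optimizer tolerance — asserted in the test
suite for coefficients, standard errors, variance components and
log-likelihood, for both REML and ML — at a fraction of the cost, which is
what makes the replicated simulation checks tractable. Fits with both
participant and cluster intercepts (the lagged model) delegate to
`lme4::lmer`.

Numerical details: the search interval is `log(theta)` in [-15, 15] with the
boundary snapped to exactly 0 when the OLS criterion is at least as good; a
constant response returns zero slopes and zero variance components rather
than failing; singular fixed-effect designs raise an error naming the aliased
columns; user-facing fits sort rows into a canonical order first, so
estimates are bit-identical under row permutations.

## What the generator emulates — and what it does not

`sim_config()` defaults *are* the emulated study conditions: the 6 cluster
sizes, 3 sequences with crossovers at 8/16/24 weeks, 5 waves 8 weeks apart,
and covariate marginals matching the baseline table (85.6% female, age
45.01 (SD 11.17) truncated to 18–70, occupations 42.4/26.8/30.8%, 81.6%
nontemporary contracts, 9.8% trainees). Score columns carry the instruments'
baseline means and SDs; the focal mediation path defaults to the printed
resilience magnitudes `a = 2.62`, `b = -0.48`, `c' = -2.77` on the CD-RISC →
PSS pair.

Mediator and outcome follow linear random-intercept equations (see
`?generate_trial`). Points that deserve emphasis:

* **Variance components are free parameters.** The trial's ICCs and residual
  variances are not published; defaults (mediator 5/4, outcome 4/3.5
  participant/residual SD) were chosen once so that marginal outcome SDs land
  near the printed baseline SDs (PSS ≈ 6.3). They are configurable and no
  test depends on their exact values.
* **The wave-1 outcome is a pre-intervention trait.** It is generated as
  intercept + covariates + noise, *without* the mediator coupling. If wave-1
  already contained `b * M_1`, adjusting for baseline would misspecify the
  analysis model and visibly attenuate the b-path; generating baseline as a
  trait measurement makes the baseline-adjusted models correctly specified,
  so path recovery is exact in expectation.
* **No secular time trend by default.** The analysis models adjust for
  cluster and baseline but not calendar time, and in a stepped wedge the
  treatment indicator is strongly confounded with time. Nonzero
  `time_slope_*` values are supported precisely to study that bias; with the
  defaults the generator and the analysis model agree.
* **Cluster random intercept defaults to 0** for the outcome (the mediation
  models adjust for cluster as a fixed covariate); a nonzero value is used
  when exercising the participant+cluster lagged model.
* **Determinism.** Each participant (and cluster) draws from its own
  deterministic substream derived from the master seed, so panels are
  bit-identical across runs and unaffected by row order or process count.
* **Not emulated:** ordinal item-level responses (scores are continuous;
  clipping to instrument ranges is an opt-in realism flag that breaks exact
  linear recovery), informative dropout (attrition is a monotone geometric
  process independent of outcomes), and cluster-level recruitment. Passing
  tests therefore demonstrate correctness of the *estimators under the
  stated generative model*, not robustness to ordinal measurement or
  outcome-dependent missingness.

## The lagged model

`fit_lagged()` predicts the outcome at wave t+1 from the mediator at wave t,
controlling for the prior outcome, treatment (at the predicted wave, by
default) and time, with participant and cluster random intercepts. The
companion generator `generate_lagged_trial()` makes the outcome an AR(1)
process with the lagged mediator entering at a known coefficient. Because
the estimator conditions on the prior outcome, a true participant intercept
on the outcome would induce dynamic-panel (Nickell-type) bias that this
estimator does not address; the generator therefore carries persistence in
the AR coefficient and defaults the participant intercept SD to 0
(overridable), which is the model the estimator assumes.

## Problem sizes used by the test suite

Replicated Monte-Carlo checks use a quarter-scale design (cluster sizes
20/12/15/19/14/7, same sequence geometry) chosen as the package's own
simulation design: parameter recovery runs 50 trials at the *full* default
design; size and coverage of the bootstrap test run 200 trials each at
quarter scale with 200 bootstrap iterations; lagged recovery runs 50
replicates. Structural tests use a 3-cluster design of 30 participants.

## Known limitations

* Only random intercepts are supported (no random slopes, no crossed designs
  beyond participant + cluster).
* Causal estimands are limited to the product of coefficients under
  linearity and no exposure–mediator interaction; natural direct/indirect
  effects and moderated mediation are out of scope.
* The sign-crossing p-value has resolution `2/n_boot`; with 1000 iterations
  p-values below 0.002 are only bounded.
* Complete-case handling assumes missingness unrelated to outcomes
  conditional on covariates, matching the generator's dropout process but
  not necessarily real attrition.
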