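---
title: "Models and methods behind sdtruth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sdtruth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sdtruth` implements a two-stage Bayesian analysis of binary
truth-judgements of political statements: a zero-one-inflated beta (ZOIB)
mixed model that converts bounded slider ratings into a political valence
per statement, and a hierarchical equal-variance signal detection theory
(SDT) model that regresses truth discernment (d') and response bias (c) on
cognitive and political predictors. This vignette records the modelling
assumptions, the defaults and why they were chosen, and the numerical
decisions a maintainer would want to know about.

## The detection model and its assumptions

Each judgement is `sayTRUE ~ Bernoulli(Phi(d' * isTRUE - c))`. The
equal-variance SDT reading places the internal evidence for false
statements at zero: `c` is therefore measured *from the false-statement
distribution*, and the familiar ideal-observer criterion is `c - d'/2`.
All closed-form comparisons in the tests use that shift; the model itself
never re-centres, because the presentation convention is absorbed by the
criterion intercept.

Both d' and c carry the same linear structure: an intercept, the
standardized CRT score, standardized political concordance, their
interaction (the only interaction in the model), the standardized numeracy
score, standardized age, and treatment-coded education with "high-school
complete" as the reference. Crossed random intercepts capture
by-participant and by-statement variability; random slopes are not
modelled. The "no-controls" sensitivity variant drops age and education
only.

Assumptions worth keeping in mind: equal variances for the true and false
evidence distributions, no lapse/guessing parameters, and conditional
independence of trials given the random intercepts.

## The calibration model

The two slider ratings (pro-Left and pro-Right congruence) are modelled
jointly as two ZOIB likelihoods sharing the participant grouping but with
fully separate coefficient sets; no residual cross-rating correlation is
modelled because the model specifies none. The beta mean gets a
logit-linked linear model (statement effects with statement 1 as
reference, political profile with "other" as reference, standardized age,
education); precision, the binary-rating probability `alpha` and the
one-given-binary probability `gamma` are intercept-only with by-rater
variability. Ratings within `1e-9` of 0 or 1 are treated as the point
masses — sliders report floating point, and anything closer than that to
the boundary is indistinguishable from it.

A statement's expected congruence for an "average participant" evaluates
the mixture mean `(1 - alpha) * mu + alpha * gamma` at random intercepts
zero, age at its mean, and an *unweighted* average over the political and
education categories (a balanced grid). Weighting by observed rater
frequencies instead is available via `marginal = "observed"`; the balanced
grid is the default because the estimand is a population-neutral
statement property, not a property of the particular rater pool. Valence
is expected pro-Right minus pro-Left congruence, in [-1, 1].

## Priors

The printed model specification does not pin prior families, so the
package uses proper, weakly informative defaults, all overridable:

* SDT fixed effects (standardized scale): Normal(0, 1); intercepts
  Normal(0, 2). Propriety is required because Savage–Dickey Bayes factors
  divide by the prior density at zero.
* Random-intercept scales: half-Normal(0, 1).
* ZOIB logit-scale fixed effects: Normal(0, 1.5); the log-precision
  intercept Normal(2, 2), a diffuse prior on a positive-support scale
  centred at a typical slider precision of ~7.

## Samplers

The SDT model is fitted by truncated-normal data augmentation: given
latent normal decision variables, every update (fixed effects, random
intercepts, scales) is conjugate Gaussian. Three standard refinements make
the geometry robust and were each adopted after observing the
corresponding pathology on simulated data:

* **Non-centered random intercepts** (`effect = lambda * u`, `u ~ N(0,1)`,
  `lambda` unconstrained Normal so `|lambda|` is half-Normal): removes the
  funnel when a variance component is near zero.
* **ASIS scale moves**: holding `lambda * u` fixed, the scale is redrawn
  from its centered conditional by slice sampling. Only
  likelihood-identified effects enter this move — d'-side intercepts of
  units never observed with a true statement are prior-only and would
  otherwise feed the scale estimate back to itself.
* **Translation interweaving**: a Gaussian move shifting mass between each
  equation intercept and the mean of its random-effect family, which the
  likelihood cannot distinguish. With only 30 statements this ridge is
  otherwise the slowest direction in the model.

Defaults are 4 chains x 2000 retained draws (8000 total) after 500
warm-up iterations. Convergence is summarised per parameter by the
split-chain potential scale reduction factor and effective sample size
(via coda); any Rhat above 1.1 flags the fit with a warning and
`converged = FALSE`. The recovery and power wrappers gate each replicate
on the diagnostics *of the parameters being tracked* (the global flag is
recorded alongside): intercept-adjacent nuisance parameters mix an order
of magnitude slower than the registered coefficients and would otherwise
discard replicates whose reported quantities are sound.

The ZOIB model is fitted with JAGS. The likelihood factorizes exactly into
a beta block over interior ratings and two Bernoulli blocks over the point
masses, which is how it is coded. Participant-level covariates (political
profile, age, education) are folded into the mean of the by-rater
intercept rather than the trial-level predictor — mathematically
identical, but it turns their conditionals conjugate-normal and removes
the intercept/covariate ridge that otherwise dominates JAGS run time.
Chains are seeded explicitly, so fits are reproducible.

## Hypothesis tests and Bayes factors

The four registered tests are directional: the proportion of posterior
draws strictly on the hypothesized side of zero, with "reliable" declared
only strictly above 0.95 (exactly 0.95 is not reliable; draws exactly at
zero count to neither side). Savage–Dickey Bayes factors use a Gaussian
kernel density with Silverman's bandwidth at the null — but only while the
null lies within 3.5 posterior standard deviations of the posterior mean.
Beyond that a finite sample contains essentially no draws near the null,
any kernel estimate is dominated by the sample minimum (errors of several
orders of magnitude on a conjugate test problem), so the estimator
switches to a moment-based normal approximation. The returned value
records which branch was used; both can be forced.

## The synthetic-study generator

`simulate_study()` draws complete studies — statements with target
valences on an evenly spaced grid over [-0.8, 0.8], participants with
demographics, item-level CRT/numeracy responses, detection trials and
calibration ratings — from known parameters, and keeps all latent truth
for recovery testing. Defaults and their rationale:

* Generating effects: concordance effect on the criterion -0.66 (the
  headline effect size this design targets), CRT effects 0.1 on both
  equations and interaction -0.1 (small standardized effects), d'-side
  concordance effect 0.08. The effect sizes used in the original
  registered power analysis are not printed in the main text, so these are
  configurable placeholders, chosen once.
* Random-intercept SDs 0.5 (participants) and 0.4 (statements): moderate
  heterogeneity, large enough that ignoring the hierarchy would visibly
  bias the fixed effects.
* Age truncated-normal (mean 58, SD 12.2, floor 18), matching the kind of
  older online volunteer sample the task was designed around; four
  education levels; polarised main-app sample, calibration sample with a
  22% non-polarised share.
* Response times log-normal (detection ~3 s median, test items ~9 s
  median) — the analysis only ever uses filter windows, so only the mass
  near the (750 ms, 10 s) and (1 s, 60 s) boundaries matters.
* ZOIB: alpha 0.1, gamma 0.5, phi 8 — occasional extreme slider use,
  symmetric, moderately precise interior ratings. Statement-level beta
  means are solved from the target valences through the mixture mean, so
  the generator's stored valence is exactly the estimand the calibration
  model marginalizes to.
* `inject_quality_violations()` plants fast trials, insincere,
  non-polarised and non-national participants at configurable rates so the
  registered exclusion rules can be exercised.

What the generator does *not* emulate: real statements and their semantic
content, correlated demographics (education, age and politics are drawn
independently), item-level difficulty correlations, slow drifts or
sequential effects in responding, and participant dropout (timed-out
trials are simply absent rows). Passing tests therefore show that the
estimation machinery recovers the generating process; they cannot show
that the model is a faithful account of human raters.

## Preprocessing rules

Inequalities are strict exactly as the criteria are worded: a detection
trial counts as in-window when 750 ms < RT < 10 s (the trial-level filter
applies only the 750 ms floor), test items when 1 s < RT < 60 s. The 75%
rule divides by the number of trials presented and passes at exactly 75%.
Test scores count correct responses among RT-valid items only — the
alternative reading (count all items, use validity only for inclusion) is
a one-line change in `score_test()` flagged for sensitivity analysis.
Standardization happens after all exclusions: CRT, numeracy and age over
retained participants, concordance over retained trials, with constants
stored for inverse mapping. A constant variable is a hard error, not a
silent zero-division.

## Problem sizes and runtime choices

The test suite and the acceptance script run everything at desk scale,
chosen so the full battery completes in minutes: recovery at 200–300
participants with reduced draw counts (2 chains x 600–1500), the
closed-form oracle at 200 x 30 trials, power trends on a 40–160 grid, and
calibration fits with 40–100 raters. The full registered configuration
(N = 1200, 8000 draws) runs through exactly the same functions and is the
default for `fit_sdt()`; reproducing the registered Bayes-factor
thresholds additionally requires supplying the original generating effect
sizes, which must come from the study's deposited scripts.

## Known limitations

* The ZOIB binary-branch variance parameters (`sd` of the alpha and gamma
  intercepts) are weakly identified at desk-scale rater counts and can
  keep Rhat slightly above 1.1 in short runs; the valence estimand is
  insensitive to them, but the honest flag will show it.
* The Savage–Dickey normal-approximation branch assumes approximate
  posterior normality of the coefficient — accurate for these
  regression-type parameters, not for boundary-constrained ones.
* No unequal-variance SDT, lapse parameters, random slopes, ordinal
  slider models, or drift-diffusion extensions.
* `read_study_tables()` validates schemas but does not attempt type
  coercion beyond what CSV parsing provides; externally deposited layouts
  are adapted through the schema mapping, which must be confirmed against
  their codebooks.
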