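---
title: "Modelling meta-learning in infant gaze behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling meta-learning in infant gaze behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gazemeta` implements a computational account of how 8-month-old infants
re-weight the informational value of visual events as they accumulate
experience with a task — *meta-learning*: changing how one learns, not just
what one knows. This vignette explains the model, the choices behind the
implementation, and what the package's simulations do and do not establish.

## The task and the ideal observer

Infants watch 16 sequences of up to 15 cue–target trials. In each sequence
the target appears in one of `K = 4` screen quadrants, favouring one
high-likelihood quadrant on 60%, 80% or 100% of trials (6, 6 and 4
sequences respectively; the session always opens with a fully predictable
sequence). `generate_task_design()` realises these rates as exact
within-sequence counts (9, 12, 15 of 15) because the experimental sequences
were fixed and shared across participants; it also enforces an exact 25%
marginal per quadrant over the 240 trials and at least two distinct
low-probability locations per probabilistic sequence. Within those
constraints, level order (after the first sequence), location labels,
off-trial identities and trial order are pseudo-randomised by the seed; an
explicit trial-location override supports replicating a specific printed
schedule.

A Bayes-optimal learner tracks a Dirichlet–categorical belief per sequence,
starting from the uniform pseudo-counts `[1, 1, 1, 1]` (each quadrant at
25%) and resetting at every sequence boundary — nothing in the task carries
location information across sequences, and empirical information-gain
traces restart high at each new sequence. After `t` within-sequence
observations the posterior-predictive probability of location `i` is
`(count_i + 1) / (t + 4)`. The information gain of a trial is the
Kullback–Leibler divergence between the predictive distribution after and
before the observation, in nats (the base is not substantive; it rescales
the weighting kernel and regression coefficients jointly and is recorded
here as the package convention).

## The meta-learning weighting kernel

Weighted information gain is

```
IG[s, t] = (la0 + la1 * s) * exp(-t * (ba0 + ba1 * s)) * D_KL[s, t]
```

with 1-based sequence index `s` and trial index `t`. `la1 > 0` means later
sequences *up-weight* information early in a sequence; `ba1 > 0` means
later sequences discount late-trial information faster (*down-weighting*).
Two readings of the rendered decay are possible — rate form
`exp(-t * (ba0 + ba1 s))` or time-constant form `exp(-t / (ba0 + ba1 s))`;
the package uses the rate form because only there does a positive `ba1`
mean stronger late-trial down-weighting in later sequences, which is how
the estimated positive slope is interpreted scientifically. The four model
variants clamp slopes to zero: `null` (neither), `upweight` (`la1` free),
`downweight` (`ba1` free), `full` (both free); `la0` and `ba0` are free in
all variants.

## Observation model

Three gaze measures share the single weighting kernel:

* look-away (trial-terminating disengagement): Bernoulli with logit link;
* saccadic latency: Gaussian on a standardised (z-scored) millisecond
  scale, negative values being anticipations;
* looking time: Gaussian on standardised log-milliseconds.

Every channel's mean is linear in `IG[s, t]` with a group-level coefficient
plus a per-infant deviation (random intercepts and random IG slopes), a
trial-number covariate, and a linear baseline-attention drift across
sequences (the `λ_s` term) that separates fatigue from meta-learning.
Covariates are centred (trial at 8, sequence at 8.5) to decorrelate
intercepts and slopes. Trials after a look-away contribute nothing; the
look-away trial itself contributes only to the look-away likelihood.

**Priors.** Group DV coefficients: Normal(0, 25²) — the weighted-IG
regressor has standard deviation of order 0.1, so coefficients of order
10–50 are plausible and unit-scale priors would be actively misspecified.
Covariate and attention slopes: Normal(0, 1). Subject-deviation and
residual scales: half-Normal(0, 1). Up-/down-weighting slopes `la1`, `ba1`:
Normal(0, 1), with kernel validity over `s = 1..16` enforced as support.
`ba0`: half-Normal(0, 1). `la0`: LogNormal(0, 0.3). The last is an
*identification* prior: the kernel scale multiplies every DV coefficient,
so only products are likelihood-identified; pinning `la0` near 1 resolves
the multiplicative degree of freedom without constraining any identified
quantity. All hyperparameters are exposed in `prior_spec()`.

## Posterior computation

The posterior mixes three awkward geometries: a logistic channel, a
centred hierarchy over 73 infants, and a nonlinear four-parameter kernel
whose scale trades off against every coefficient. `fit()` runs a blocked
sampler written for this structure:

* exact conjugate Gibbs draws for the Gaussian channels' per-infant
  (intercept, slope) pairs, covariate slopes and all group means;
* adaptive random-walk Metropolis for the look-away channel's subject
  effects (vectorised across infants), its covariate slopes, and the
  variance parameters (log scale);
* an adaptive multivariate random-walk block for the weighting kernel
  (`log la0` plus the free slopes and `ba0` on their natural scale, where
  their posterior correlation is linear), with a fixed-scale mixture
  component and a floored adapted covariance so adaptation cannot
  collapse;
* three dedicated *structural* moves that traverse the posterior's ridges:
  a multiplicative scale move rescaling (`la0`, `la1`) against all IG
  coefficients jointly; translation moves shifting each group mean together
  with its subject effects; and spread moves contracting/expanding each
  random-effect cloud together with its deviation SD (funnel traversal).

Proposal scales adapt toward standard acceptance targets during warm-up and
are frozen afterwards. Defaults are 2 chains × (1,500 warm-up + 1,500 kept)
draws — the package's desk-scale working budget; study-scale validation
uses 2,000 + 2,000, and `fit_config(paper_scale = TRUE)` reproduces the
long-run budget (390,000 warm-up, 10,000 kept). Convergence is declared
when the maximum split R-hat over all parameters is below 1.05; split
R-hat, effective sample size and the 94% highest-density interval
(narrowest contiguous interval) are computed in-package and verified
against brute-force implementations in the tests.

Model comparison uses the negative expected log pointwise predictive
density per dependent variable and in total, estimated both by WAIC and by
Pareto-smoothed importance-sampling LOO (implemented from the pointwise
log-likelihood draws; the generalized-Pareto tail fit follows the standard
profile-likelihood recipe). Differences from the null variant are reported
with standard errors from the pointwise ELPD differences.

## The synthetic cohort

`simulate_cohort()` generates data with the statistical structure the
analysis assumes, so the whole pipeline is testable without the study's
eye-tracking recordings:

* **Effect sizes.** The DV coefficient defaults (−4.98 look-away, 0.69
  saccadic latency, −0.57 looking time) and the down-weighting slope
  (`ba1 = 0.065`, `la1 = 0`) are the study's reported group posterior
  means. The kernel intercepts are not printed in the study; the generator
  uses `ba0 = 0.1` and calibrates the kernel scale to `la0 = 8` so that
  full-model fits on simulated cohorts reproduce the *reported posterior
  SDs* of the DV coefficients (≈0.6 logit for look-away, ≈0.2 standardised
  for the Gaussian channels, on the product scale). Only the product of
  kernel scale and coefficients is identified, so this calibration fixes
  the simulation's information content, not its conclusions.
* **Truncation.** Look-away is drawn per trial; the first look-away ends
  the sequence, the look-away trial keeps only its binary outcome, and
  later trials are missing — monotone missingness within sequence.
* **Dropout.** Sessions end by a per-sequence geometric hazard calibrated
  in closed form (`calibrate_dropout()`) so infants watch 7 of 16 sequences
  on average, emulating fussiness-driven attrition. This is a calibrated
  stand-in, not a claim about the study's attrition process.
* **Noise models.** Saccadic latency is Gaussian around 400 ms (150 ms per
  standardised unit, so anticipations occur naturally); looking time is
  log-normal around 1.5 s (guaranteeing positivity); look-away baseline is
  logit −2.9 per trial. Between-infant SDs: 1.0 (look-away) and 0.3
  (Gaussian channels) on the coefficient scale, 0.5/0.3/0.3 on baselines.
  Trial slopes (0.05, −0.01, −0.02) and attention drifts (0.05, 0.01,
  −0.02) are modest fatigue-like trends. These values are package choices
  of realistic magnitudes, stated here once; none is printed in the study.

Two validation regimes are used deliberately. Parameter recovery runs at
the study's reported effect sizes (`ba1 = 0.065`): the full model's 94%
HDIs cover the generating slope and cover zero for the absent up-weighting.
Model-*comparison* validation instead uses a stronger down-weighting cohort
(`ba1 = 0.2`): with sequence truncation and session dropout, the
out-of-sample ELPD separation between variants saturates at a few points
however strong the slope (late-sequence cells that would discriminate the
kernels are exactly the ones missing), and an up-weight kernel can imitate
down-weighting through a negative scale slope, so at `0.065` the variant
ordering is within noise even though the parameter is recoverable. The
stronger condition checks that the comparison machinery resolves the
ordering when the data can support it.

What passing tests on such cohorts show: the pipeline recovers known
weighting parameters, orders model variants correctly when the signal
supports ordering, and is calibrated at the study's size and missingness. What they do not show: robustness to
fixation-extraction noise, non-geometric attrition, non-Gaussian latency
tails, or any violation of the linear-in-IG mean structure — properties of
real infant data that the generator deliberately does not emulate.

## Downstream analyses

`simulate_unseen_sequence()` propagates the fitted kernel posterior to a
held-out sequence (default: sequence 16) as if it had been encountered at
different session positions, with credible bands over posterior draws —
with down-weighting and no up-weighting, the later-position curve starts at
the same level and falls below the earlier-position curve over trials.

`fit_efficiency_model()` is the learning-efficiency analysis: saccadic
latency on predictable trials (target at the sequence's high-likelihood
location, first trial of each sequence excluded, response standardised) as
a linear function of sequence number, the natural log of the 1-based
within-sequence trial index, their interaction and the overall trial
number, all centred, with per-infant random intercepts and random slopes
for every predictor (independent scales). It runs on the same blocked-Gibbs
machinery. Marginal effects of sequence number are reported at each trial
index with the overall-trial covariate held at its mean.
`simulate_efficiency_cohort()` builds validation data for this analysis
from the mixed model's own generative form; its default interaction
strength (0.08 standardised units per sequence × log-trial) is set high
enough that a 73-infant cohort detects it with high power — a detection
validation, intentionally stronger than the small empirical interaction a
real cohort would show.

## Numerical and degenerate-case choices

* Exact 25% marginals are found by a seeded randomized search (balanced
  round-robin high-location assignment, then max-deficit-first placement
  of off-trials under per-sequence caps that force ≥ 2 distinct
  low-probability locations), with restart on the rare dead end and a
  configuration error when a schedule is genuinely infeasible.
* KL divergence is evaluated only on strictly positive distributions
  (guaranteed by the Dirichlet smoothing); zero or negative inputs raise.
* The weighting kernel hard-checks validity (`la0 + la1 s > 0`,
  `ba0 + ba1 s ≥ 0`) over the trace's sequence range in forward
  evaluation, naming the first offending sequence; during inference the
  same constraint is the prior's support.
* Ties in the HDI (equal-width windows) resolve to the first (lowest)
  window; HDI mass defaults to 0.94.
* `posterior_predictive(..., ndraws = 0)` returns empty replicate matrices
  without error; a header-only gaze table reads as an empty valid table.
* MCMC fits, cohort simulation and the design generator are deterministic
  given their seeds; fits restore the caller's RNG state.

## Known limitations

* The weighting kernel is estimated at the group level only (as in the
  study); per-infant meta-parameters would need a different hierarchy.
* The kernel-scale split between `la0` and the DV coefficients is set by
  the identification prior; comparisons of raw coefficient magnitudes
  across studies must use products.
* PSIS-LOO diagnostics (Pareto k) are reported but high-k points are not
  refit exactly; with the smooth likelihoods used here k is essentially
  always below 0.7.
* The efficiency model uses independent random-effect scales (no
  correlation between an infant's slopes), a common simplification.
* With 60%-predictability sequences, the ideal observer's trace depends on
  the realised trial order; analyses that need the experiment's exact
  printed order should inject it via the design's trial-locations override.
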