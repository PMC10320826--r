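# gazemeta

Hierarchical Bayesian modelling of how infants re-weight the informational
value of visual events as they gain experience with a task.

## The scientific problem

In probabilistic cueing experiments, 8-month-old infants watch sequences of
cue–target trials in which the target favours one of four screen locations.
Early trials of a sequence carry most of the information about that
sequence's structure; late trials are largely redundant. If infants
*meta-learn* — use experience with earlier sequences to change how they
process later ones — the informational value they assign to a stimulus
should shift across the session: late-trial evidence should be
progressively down-weighted (and early-trial evidence possibly up-weighted)
as sequences accumulate. `gazemeta` is for developmental and computational
cognitive scientists who want to fit, validate and extend this analysis:
it reconstructs the full pipeline from task structure to posterior
inference and model comparison, with a calibrated synthetic-cohort
generator standing in for raw eye-tracking data.

## The model

An ideal observer tracks a Dirichlet–categorical belief over the K = 4
target locations, reset at each sequence, with uniform prior pseudo-counts
γ = [1,1,1,1]:

    P(X)_{s,t} = (X_{s,t} + γ) / (t + K)

The information gain of the trial-`t` stimulus in sequence `s` is the
Kullback–Leibler divergence between consecutive predictive distributions
(in nats):

    D_KL[s,t] = Σ_i P(X)_{s,t,i} · log( P(X)_{s,t,i} / P(X)_{s,t−1,i} )

A meta-learning kernel re-weights this information across the session:

    IG[s,t] = (λα0 + λα1·s) · exp(−t·(βα0 + βα1·s)) · D_KL[s,t]

λα1 > 0 is early up-weighting across sequences; βα1 > 0 is late
down-weighting across sequences. Three gaze measures share this kernel in
one hierarchical observation model — look-away (Bernoulli-logit, ends the
sequence), saccadic latency (Gaussian, standardised ms) and looking time
(Gaussian, standardised log-ms) — each with a group-level IG coefficient,
per-infant random intercepts and IG slopes, a trial-number covariate and a
baseline attention drift λ_s across sequences. Four variants (null /
upweight / downweight / full) clamp λα1 and βα1 to zero in the obvious
combinations and are compared by −ELPD (PSIS-LOO and WAIC). Fitting is by
blocked Gibbs/adaptive-Metropolis MCMC written for this posterior (see the
methods vignette), with split-R̂ < 1.05 as the convergence bar.

## Worked example

```r
library(gazemeta)

design <- generate_task_design(seed = 1)
design
#> <task_design> 16 sequences x 15 trials, 4 locations; levels: 60% x6, 80% x6, 100% x4

trace <- info_trace(design)
round(trace$d_kl[trace$sequence == 1][1:5], 4)
#> [1] 0.0541 0.0204 0.0102 0.0059 0.0038

# a small synthetic cohort, then a reduced-draws fit for speed
cohort <- apply_exclusion(simulate_cohort(design, cohort_config(n_infants = 20), seed = 5))
mean(sequences_watched(cohort)$n_sequences)
#> [1] 9.333333

model <- build_model("full", cohort, design)
model
#> <gaze_model> variant 'full' (free kernel params: la0, la1, ba0, ba1)
#>   18 infants; likelihood terms: LA 2083, SL 2012, LT 2012

fit_res <- fit(model, fit_config(chains = 2, tune = 1000, draws = 1000, seed = 3))
fit_res
#> <gaze_fit> variant 'full': 2 chains x 1000 draws; max split R-hat 1.032 (converged)

summarize_fit(fit_res, c("ba1", "la1", "mu_b_la"))
#> # A tibble: 3 x 8
#>   parameter    mean     sd hdi_lower hdi_upper  rhat    ess nonzero
#>   <chr>       <dbl>  <dbl>     <dbl>     <dbl> <dbl>  <dbl> <lgl>
#> 1 ba1         0.613  0.618   -0.0314      1.90  1.01  73.8  FALSE
#> 2 la1         0.669  0.541   -0.0773      1.66  1.00 299.1  FALSE
#> 3 mu_b_la   -19.4   24.7   -64.2         27.4   1.01 100.2  FALSE
```

The first trial of every sequence carries 0.0541 nats (the step away from
the uniform prior); repeated confirmations decay roughly geometrically
(0.0204, 0.0102, ...). Two of the 20 simulated infants fall under the
20-trial inclusion rule. At this toy size the weighting posteriors are
still wide — 18 infants cannot pin a four-parameter kernel — which is the
expected behaviour; at the study's size (73 infants) the down-weighting
slope is recovered with 94% HDIs covering the generating value and the
look-away coefficient is credibly negative. That study-scale behaviour
(replicate recovery, variant comparison, convergence) is exercised in
`tests/testthat/test-acceptance.R`.

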