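# Shared fixtures, built lazily and cached for the test run. Expensive MCMC
# fits are computed once and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

ref_design <- function() fixture("design", function() generate_task_design(seed = 1))

# small cohort + full-variant fit used by the unit tests (not the
# acceptance suite, which runs at study scale)
small_cohort <- function() fixture("small_cohort", function() {
  simulate_cohort(ref_design(), cohort_config(n_infants = 20), seed = 5)
})

small_fit <- function() fixture("small_fit", function() {
  m <- build_model("full", small_cohort(), ref_design())
  fit(m, fit_config(chains = 2, tune = 1000, draws = 1000, seed = 3))
})

# brute-force predictive oracle: recompute counts from a raw observation
# list and normalise with the prior pseudo-counts
oracle_predictive <- function(observations, prior = c(1, 1, 1, 1)) {
  counts <- tabulate(observations, nbins = length(prior))
  (counts + prior) / (length(observations) + sum(prior))
}

# mock multi-chain draws with controlled autocorrelation
mock_chains <- function(n = 500, chains = 2, rho = 0.5, seed = 42,
                        shift = 0) {
  set.seed(seed)
  sapply(seq_len(chains), function(ch) {
    x <- numeric(n)
    x[1] <- rnorm(1)
    for (i in 2:n) x[i] <- rho * x[i - 1] + sqrt(1 - rho^2) * rnorm(1)
    x + shift * (ch - 1)
  })
}
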