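# textbook implementations used as oracles (straight loops, no shortcuts)

oracle_split_rhat <- function(x) {
  n <- nrow(x); half <- floor(n / 2)
  halves <- list()
  for (j in seq_len(ncol(x))) {
    halves[[length(halves) + 1]] <- x[1:half, j]
    halves[[length(halves) + 1]] <- x[(n - half + 1):n, j]
  }
  m <- length(halves); nh <- half
  means <- sapply(halves, mean)
  W <- mean(sapply(halves, var))
  B <- nh / (m - 1) * sum((means - mean(means))^2)
  var_plus <- (nh - 1) / nh * W + B / nh
  sqrt(var_plus / W)
}

oracle_hdi <- function(x, mass) {
  x <- sort(x); n <- length(x); k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - k)) {
    if (x[i + k] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + k])
  }
  best
}

test_that("split R-hat matches a textbook implementation to 1e-8", {
  for (seed in 1:5) {
    x <- mock_chains(n = 400, chains = 2, rho = 0.6, seed = seed)
    expect_equal(split_rhat(x), oracle_split_rhat(x), tolerance = 1e-8)
  }
  # shifted chains are flagged
  bad <- mock_chains(n = 400, chains = 2, rho = 0.3, seed = 7, shift = 3)
  expect_gt(split_rhat(bad), 1.5)
  good <- mock_chains(n = 2000, chains = 2, rho = 0.2, seed = 8)
  expect_lt(split_rhat(good), 1.02)
})

test_that("effective sample size shrinks with autocorrelation and is sane for iid draws", {
  set.seed(1)
  iid <- matrix(rnorm(4000), ncol = 2)
  e_iid <- ess_mean(iid)
  expect_gt(e_iid, 3000)
  expect_lt(e_iid, 5200)

  cor_chain <- mock_chains(n = 2000, chains = 2, rho = 0.9, seed = 2)
  e_cor <- ess_mean(cor_chain)
  expect_lt(e_cor, e_iid / 5)
  # AR(1) theory: ESS ~ N * (1-rho)/(1+rho)
  expect_equal(e_cor, 4000 * 0.1 / 1.9, tolerance = 0.5)
})

test_that("HDI is the narrowest contiguous interval at the requested mass", {
  set.seed(3)
  for (rep in 1:20) {
    x <- rgamma(600, shape = 2)
    h <- hdi(x, 0.94)
    o <- oracle_hdi(x, 0.94)
    expect_equal(unname(h), o, tolerance = 1e-12)
    inside <- mean(x >= h[1] & x <= h[2])
    expect_gte(inside * length(x), floor(0.94 * length(x)) - 1)
  }
  # asymmetric distribution: HDI differs from the central interval
  x <- rexp(5000)
  h <- hdi(x, 0.9)
  expect_lt(h[["lower"]], quantile(x, 0.05))
})

test_that("WAIC matches a hand-loop computation", {
  set.seed(5)
  ll <- matrix(rnorm(200 * 30, mean = -1), 200, 30)
  w <- waic(ll)
  elpd_hand <- 0; p_hand <- 0
  for (i in 1:30) {
    lpd_i <- log(mean(exp(ll[, i])))
    p_i <- var(ll[, i])
    elpd_hand <- elpd_hand + lpd_i - p_i
    p_hand <- p_hand + p_i
  }
  expect_equal(w$elpd, elpd_hand, tolerance = 1e-10)
  expect_equal(w$p_eff, p_hand, tolerance = 1e-10)
})

test_that("PSIS-LOO agrees with exact leave-one-out on a conjugate normal model", {
  # y_i ~ N(mu, 1), mu ~ N(0, 10^2): exact LOO predictive is available in
  # closed form, and posterior draws are exact normal draws.
  set.seed(6)
  n <- 40
  y <- rnorm(n, 0.7, 1)
  post_var <- 1 / (n + 1 / 100)
  post_mean <- sum(y) * post_var
  S <- 4000
  mu_draws <- rnorm(S, post_mean, sqrt(post_var))
  ll <- sapply(y, function(yi) dnorm(yi, mu_draws, 1, log = TRUE))
  loo <- psis_loo(ll)

  exact <- sum(sapply(seq_len(n), function(i) {
    v_i <- 1 / (n - 1 + 1 / 100)
    m_i <- sum(y[-i]) * v_i
    dnorm(y[i], m_i, sqrt(1 + v_i), log = TRUE)
  }))
  expect_equal(loo$elpd, exact, tolerance = 0.02)
  expect_true(all(loo$pareto_k < 0.7, na.rm = TRUE))

  # LOO and WAIC agree on this well-behaved model
  expect_equal(loo$elpd, waic(ll)$elpd, tolerance = 0.05)
})

test_that("summaries report HDI mass correctly on mock draws", {
  f <- small_fit()
  s <- summarize_fit(f, c("ba1", "mu_b_la"))
  for (k in 1:2) {
    x <- as.vector(f$draws[, , s$parameter[k]])
    inside <- sum(x >= s$hdi_lower[k] & x <= s$hdi_upper[k])
    expect_gte(inside, floor(0.94 * length(x)) - 1)
    expect_lte(inside, ceiling(0.955 * length(x)))
  }
})
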