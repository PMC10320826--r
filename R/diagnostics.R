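#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (rank-free version): with m half-chains of length n,
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` where `W` is the mean
#' within-half-chain variance and `B` the between-half-chain variance.
#' Values below 1.05 are taken as converged here.
#'
#' @param x Numeric matrix of posterior draws, iterations x chains.
#' @return The split R-hat (scalar). `NA` if draws are constant.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(halves)
  nh <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- nh * stats::var(means)
  if (!is.finite(W) || W <= 0) {
    return(if (B == 0 || !is.finite(B)) NA_real_ else Inf)
  }
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

#' Effective sample size
#'
#' Multi-chain effective sample size using the between/within variance
#' estimate of the autocorrelation sequence and Geyer's initial monotone
#' positive sequence truncation.
#'
#' @param x Numeric matrix of posterior draws, iterations x chains.
#' @return Estimated effective sample size (scalar).
#' @export
ess_mean <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  chain_means <- colMeans(x)
  chain_vars <- apply(x, 2, stats::var)
  W <- mean(chain_vars)
  var_plus <- W * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(chain_means)
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)

  # per-chain autocovariances (biased, as in the usual estimator)
  max_lag <- n - 1
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }, numeric(max_lag + 1))
  acov <- matrix(acov, nrow = max_lag + 1)
  mean_acov <- rowMeans(acov)

  rho <- 1 - (W - mean_acov) / var_plus # rho[1] corresponds to lag 0
  # Geyer: sum pairs (rho[2t], rho[2t+1]) while positive, enforce monotone
  tau <- 1
  t <- 1
  prev_pair <- Inf
  while (t + 2 <= length(rho)) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2
  }
  max(n * m / tau, 1e-12)
}

#' Highest-density interval
#'
#' Narrowest contiguous interval containing `mass` of the draws.
#'
#' @param x Numeric vector of draws.
#' @param mass Probability mass (default 0.94).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.94) {
  stopifnot(mass > 0, mass < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}
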