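# Pointwise predictive machinery: log-likelihood matrices from stored
# draws, WAIC, Pareto-smoothed importance-sampling LOO, and the model
# comparison table.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# state list from one stored draw
.state_from_draw <- function(fit, draw_vec) {
  J <- fit$model$data$J
  g <- function(p) draw_vec[[p]]
  ch <- function(d) {
    list(a = unname(draw_vec[paste0("a_", d, "[", seq_len(J), "]")]),
         b = unname(draw_vec[paste0("b_", d, "[", seq_len(J), "]")]),
         cc = g(paste0("c_", d)), dd = g(paste0("d_", d)))
  }
  list(la0 = g("la0"), la1 = g("la1"), ba0 = g("ba0"), ba1 = g("ba1"),
       la = ch("la"), sl = ch("sl"), lt = ch("lt"),
       sig_sl = g("sig_sl"), sig_lt = g("sig_lt"))
}

#' Pointwise log-likelihood matrices from a fitted model
#'
#' Recomputes, for (a thinned subset of) the stored posterior draws, the
#' log-likelihood of every observed data point under each draw, per
#' dependent variable.
#'
#' @param fit A `gaze_fit`.
#' @param max_draws Maximum number of draws used (evenly thinned across the
#'   kept draws of all chains; default 800).
#' @return List with matrices `la`, `sl`, `lt` (draws x points).
#' @export
loglik_matrix <- function(fit, max_draws = 800L) {
  dat <- fit$model$data
  dm <- posterior_draws(fit)
  S_all <- nrow(dm)
  keep <- unique(round(seq(1, S_all, length.out = min(max_draws, S_all))))
  out <- list(la = matrix(NA_real_, length(keep), length(dat$la$y)),
              sl = matrix(NA_real_, length(keep), length(dat$sl$y)),
              lt = matrix(NA_real_, length(keep), length(dat$lt$y)))
  for (si in seq_along(keep)) {
    st <- .state_from_draw(fit, dm[keep[si], ])
    ig <- .kernel_eval(st, dat$cells)
    eta <- .eta_channel(st, "la", dat$la, ig)
    out$la[si, ] <- .ll_bern(eta, dat$la$y)
    mu <- .eta_channel(st, "sl", dat$sl, ig)
    out$sl[si, ] <- stats::dnorm(dat$sl$y, mu, st$sig_sl, log = TRUE)
    mu <- .eta_channel(st, "lt", dat$lt, ig)
    out$lt[si, ] <- stats::dnorm(dat$lt$y, mu, st$sig_lt, log = TRUE)
  }
  out
}

#' Widely applicable information criterion from a log-likelihood matrix
#'
#' @param ll Matrix of pointwise log-likelihood draws (draws x points).
#' @return List with `elpd` (sum over points), `p_eff`, `pointwise`
#'   (per-point elpd contributions) and `se`.
#' @export
waic <- function(ll) {
  S <- nrow(ll)
  lpd <- apply(ll, 2, .logsumexp) - log(S)
  p <- apply(ll, 2, stats::var)
  pointwise <- lpd - p
  list(elpd = sum(pointwise), p_eff = sum(p), pointwise = pointwise,
       se = sqrt(length(pointwise) * stats::var(pointwise)))
}

# Generalized Pareto fit to sorted exceedances (profile-likelihood weighting
# with a weak prior on the inverse-scale grid; shape regularised toward 0.5).
.gpd_fit <- function(x) {
  n <- length(x)
  if (n < 5 || x[n] <= 0) return(list(k = NA_real_, sigma = NA_real_))
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w <- exp(l_j - .logsumexp(l_j))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- k * n / (n + 10) + 0.5 * 10 / (n + 10) # weak prior toward 0.5
  list(k = k, sigma = sigma)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance weights for one point; lw are raw log weights.
.psis_weights <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- sort(exp(lw[tail_ids]) - exp(cutoff))
  fit <- .gpd_fit(exc)
  if (is.finite(fit$k) && is.finite(fit$sigma) && fit$sigma > 0) {
    q <- .qgpd((seq_len(M) - 0.5) / M, fit$k, fit$sigma)
    smoothed <- pmin(log(q + exp(cutoff)), 0)
    lw[tail_ids] <- smoothed # tail_ids already in increasing lw order
  }
  list(lw = lw, k = fit$k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' @param ll Matrix of pointwise log-likelihood draws (draws x points).
#' @return List with `elpd`, `pointwise`, `se` and `pareto_k` per point.
#' @export
psis_loo <- function(ll) {
  n <- ncol(ll)
  pointwise <- numeric(n)
  k <- numeric(n)
  for (i in seq_len(n)) {
    ps <- .psis_weights(-ll[, i])
    pointwise[i] <- .logsumexp(ll[, i] + ps$lw) - .logsumexp(ps$lw)
    k[i] <- ps$k
  }
  list(elpd = sum(pointwise), pointwise = pointwise,
       se = sqrt(n * stats::var(pointwise)), pareto_k = k)
}

#' Compare fitted model variants by -ELPD (LOO and WAIC)
#'
#' Mirrors the study's comparison layout: per dependent variable and in
#' total, the negative expected log pointwise predictive density of each
#' variant by PSIS-LOO and by WAIC, the improvement over the null variant
#' (`delta_* = null - variant`, positive favours the variant) and the
#' standard error of the pointwise ELPD difference from the null.
#'
#' @param fits Named list of `gaze_fit` objects fitted to the same data;
#'   must include a fit named `"null"` for the deltas.
#' @param max_draws Draws used for the pointwise log-likelihood (see
#'   [loglik_matrix()]).
#' @return A `comparison_table` tibble with columns `variant`, `dv`,
#'   `neg_elpd_loo`, `delta_loo`, `se_delta_loo`, `neg_elpd_waic`,
#'   `delta_waic`, `best`.
#' @export
compare_models <- function(fits, max_draws = 800L) {
  stopifnot(is.list(fits), length(fits) >= 2, !is.null(names(fits)))
  hashes <- vapply(fits, function(f) f$data_hash, character(1))
  if (length(unique(hashes)) != 1) {
    stop("model fits were computed on differing data (data hash mismatch)",
         call. = FALSE)
  }
  if (!("null" %in% names(fits))) {
    stop("compare_models requires a fit named 'null' as the reference",
         call. = FALSE)
  }

  per_fit <- lapply(fits, function(f) {
    ll <- loglik_matrix(f, max_draws)
    lapply(ll, function(m) list(loo = psis_loo(m), waic = waic(m)))
  })

  dv_labels <- c(la = "Look-Away", sl = "Saccadic Latency", lt = "Looking Time")
  rows <- list()
  for (v in names(fits)) {
    tot_loo <- tot_waic <- 0
    diff_points <- numeric(0)
    for (d in c("lt", "sl", "la")) {
      loo_v <- per_fit[[v]][[d]]$loo
      waic_v <- per_fit[[v]][[d]]$waic
      dp <- loo_v$pointwise - per_fit[["null"]][[d]]$loo$pointwise
      diff_points <- c(diff_points, dp)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variant = v, dv = dv_labels[[d]],
        neg_elpd_loo = -loo_v$elpd,
        delta_loo = sum(dp),
        se_delta_loo = sqrt(length(dp) * stats::var(dp)),
        neg_elpd_waic = -waic_v$elpd,
        delta_waic = waic_v$elpd - per_fit[["null"]][[d]]$waic$elpd
      )
      tot_loo <- tot_loo + loo_v$elpd
      tot_waic <- tot_waic + waic_v$elpd
    }
    null_tot_loo <- sum(vapply(c("lt", "sl", "la"), function(d)
      per_fit[["null"]][[d]]$loo$elpd, numeric(1)))
    null_tot_waic <- sum(vapply(c("lt", "sl", "la"), function(d)
      per_fit[["null"]][[d]]$waic$elpd, numeric(1)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variant = v, dv = "Total",
      neg_elpd_loo = -tot_loo,
      delta_loo = tot_loo - null_tot_loo,
      se_delta_loo = sqrt(length(diff_points) * stats::var(diff_points)),
      neg_elpd_waic = -tot_waic,
      delta_waic = tot_waic - null_tot_waic
    )
  }
  out <- dplyr::bind_rows(rows)
  totals <- out[out$dv == "Total", ]
  best <- totals$variant[which.min(totals$neg_elpd_loo)]
  out$best <- out$variant == best & out$dv == "Total"
  class(out) <- c("comparison_table", class(out))
  out
}

#' Write a comparison table as delimited text
#'
#' @param table A `comparison_table` from [compare_models()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
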