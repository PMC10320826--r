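#' Posterior predictive replication of the gaze measures
#'
#' Draws replicated datasets from the fitted observation model at the
#' observed design cells: look-away indicators from the Bernoulli-logit
#' channel and saccadic latency / looking time from their Gaussian channels
#' (reported back on the millisecond scale).
#'
#' @param fit A `gaze_fit`.
#' @param ndraws Number of replicated datasets (default 200; 0 gives empty
#'   matrices without error).
#' @param seed Seed for the replication noise.
#' @return List with matrices `la`, `sl_ms`, `lt_ms` (ndraws x points) and
#'   the observed vectors `observed_la`, `observed_sl_ms`, `observed_lt_ms`.
#' @export
posterior_predictive <- function(fit, ndraws = 200L, seed = 1L) {
  dat <- fit$model$data
  sc <- dat$scaling
  ndraws <- as.integer(ndraws)
  stopifnot(ndraws >= 0)
  out <- list(
    la = matrix(NA_real_, ndraws, length(dat$la$y)),
    sl_ms = matrix(NA_real_, ndraws, length(dat$sl$y)),
    lt_ms = matrix(NA_real_, ndraws, length(dat$lt$y)),
    observed_la = dat$la$y,
    observed_sl_ms = dat$sl$y * sc$sl_scale + sc$sl_center,
    observed_lt_ms = exp(dat$lt$y * sc$lt_scale + sc$lt_center)
  )
  if (ndraws == 0) return(out)

  dm <- posterior_draws(fit)
  idx <- unique(round(seq(1, nrow(dm), length.out = ndraws)))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  for (i in seq_along(idx)) {
    st <- .state_from_draw(fit, dm[idx[i], ])
    ig <- .kernel_eval(st, dat$cells)
    eta <- .eta_channel(st, "la", dat$la, ig)
    out$la[i, ] <- stats::rbinom(length(eta), 1, stats::plogis(eta))
    mu <- .eta_channel(st, "sl", dat$sl, ig)
    z <- stats::rnorm(length(mu), mu, st$sig_sl)
    out$sl_ms[i, ] <- z * sc$sl_scale + sc$sl_center
    mu <- .eta_channel(st, "lt", dat$lt, ig)
    z <- stats::rnorm(length(mu), mu, st$sig_lt)
    out$lt_ms[i, ] <- exp(z * sc$lt_scale + sc$lt_center)
  }
  # if thinning collapsed duplicate indices, trim to the realised rows
  if (length(idx) < ndraws) {
    out$la <- out$la[seq_along(idx), , drop = FALSE]
    out$sl_ms <- out$sl_ms[seq_along(idx), , drop = FALSE]
    out$lt_ms <- out$lt_ms[seq_along(idx), , drop = FALSE]
  }
  out
}
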