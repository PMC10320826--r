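# Learning-efficiency analysis: Bayesian linear mixed model for saccadic
# latencies on predictable trials, with per-infant random intercepts and
# random slopes for every within-infant predictor. Fully conjugate Gibbs
# draws for coefficients and random effects; log-scale random-walk
# Metropolis for the variance parameters.

#' Specification of the learning-efficiency model
#'
#' Saccadic latency (standardised) on predictable trials is modelled as a
#' linear function of sequence number, a logarithmic function of
#' within-sequence trial number, their interaction, and the overall trial
#' number, all centred. The first trial of each sequence is excluded and
#' only trials whose target appears at the sequence's high-likelihood
#' location are retained. Per-infant random intercepts and random slopes
#' for all predictors.
#'
#' @param exclude_first_trial Drop trial 1 of every sequence (default TRUE).
#' @param predictable_only Keep only high-likelihood-location trials
#'   (default TRUE).
#' @return An `efficiency_spec` object.
#' @export
efficiency_spec <- function(exclude_first_trial = TRUE, predictable_only = TRUE) {
  structure(list(exclude_first_trial = exclude_first_trial,
                 predictable_only = predictable_only),
            class = "efficiency_spec")
}

# filtered + centred design matrix for the efficiency model
.efficiency_data <- function(table, design, spec) {
  n0 <- nrow(table)
  high_loc <- design$sequences$high_location[
    match(table$sequence, design$sequences$sequence)]
  drop_sl <- is.na(table$saccadic_latency_ms)
  drop_first <- spec$exclude_first_trial & table$trial == 1
  drop_pred <- spec$predictable_only & table$location != high_loc
  keep <- !(drop_sl | drop_first | drop_pred)
  filter_log <- tibble::tibble(
    reason = c("missing saccadic latency (look-away trial)",
               "first trial of sequence",
               "target not at high-likelihood location"),
    rows_dropped = c(sum(drop_sl), sum(drop_first & !drop_sl),
                     sum(drop_pred & !drop_sl & !drop_first))
  )
  tab <- table[keep, ]
  if (nrow(tab) == 0) {
    stop("no predictable trials remain after filtering", call. = FALSE)
  }
  z <- as.numeric(scale(tab$saccadic_latency_ms))
  seqc <- tab$sequence - mean(tab$sequence)
  logtr <- log(tab$trial) - mean(log(tab$trial))
  overall <- (tab$sequence - 1) * design$n_trials + tab$trial
  overallc <- overall - mean(overall)
  X <- cbind(intercept = 1, sequence = seqc, log_trial = logtr,
             `sequence:log_trial` = seqc * logtr, overall_trial = overallc)
  list(y = z, X = X, subj = match(tab$infant_id, sort(unique(tab$infant_id))),
       J = length(unique(tab$infant_id)), filter_log = filter_log,
       log_trial_centering = mean(log(tab$trial)), n_used = nrow(tab),
       n_input = n0)
}

.run_efficiency_chain <- function(ed, config, chain) {
  set.seed(config$seed * 1000L + chain)
  y <- ed$y; X <- ed$X; subj <- ed$subj; J <- ed$J
  P <- ncol(X)
  n <- length(y)
  XtX_j <- lapply(seq_len(J), function(j) {
    Xi <- X[subj == j, , drop = FALSE]
    crossprod(Xi)
  })
  Xty_part <- function(resid) crossprod(X, resid)

  beta <- stats::coef(stats::lm(y ~ X - 1)) + stats::rnorm(P, 0, 0.05)
  u <- matrix(0, J, P)
  tau <- rep(0.2, P) * exp(stats::rnorm(P, 0, 0.2))
  sig <- stats::sd(y) * exp(stats::rnorm(1, 0, 0.1))
  prior_beta_sd <- 2
  step_tau <- rep(0.3, P); acc_tau <- numeric(P)
  step_spread <- rep(0.3, P); acc_spread <- numeric(P)
  step_sig <- 0.05; acc_sig <- 0
  batch <- 50L

  n_iter <- config$tune + config$draws
  par_names <- c(colnames(X), paste0("tau_", colnames(X)), "sigma")
  draws <- matrix(NA_real_, config$draws, length(par_names),
                  dimnames = list(NULL, par_names))
  ranef_mean <- matrix(0, J, P)

  XtX <- crossprod(X)
  for (iter in seq_len(n_iter)) {
    # random effects contribution per row
    u_row <- rowSums(X * u[subj, , drop = FALSE])
    # beta | rest
    prec <- XtX / sig^2 + diag(1 / prior_beta_sd^2, P)
    hvec <- crossprod(X, y - u_row) / sig^2
    ch <- chol(prec)
    m <- backsolve(ch, backsolve(ch, hvec, transpose = TRUE))
    beta <- drop(m + backsolve(ch, stats::rnorm(P)))

    # u_j | rest
    fixed_row <- drop(X %*% beta)
    r <- y - fixed_row
    for (j in seq_len(J)) {
      rows <- subj == j
      Xi <- X[rows, , drop = FALSE]
      precj <- XtX_j[[j]] / sig^2 + diag(1 / tau^2, P)
      hj <- crossprod(Xi, r[rows]) / sig^2
      chj <- chol(precj)
      mj <- backsolve(chj, backsolve(chj, hj, transpose = TRUE))
      u[j, ] <- drop(mj + backsolve(chj, stats::rnorm(P)))
    }
    u_row <- rowSums(X * u[subj, , drop = FALSE])

    # tau_k | u (log random walk, half-normal prior)
    for (k in seq_len(P)) {
      lt <- log(tau[k])
      lt2 <- lt + step_tau[k] * stats::rnorm(1)
      tgt <- function(ls) {
        s <- exp(ls)
        sum(stats::dnorm(u[, k], 0, s, log = TRUE)) +
          .half_normal_lp(s, 1) + ls
      }
      if (log(stats::runif(1)) < tgt(lt2) - tgt(lt)) {
        tau[k] <- exp(lt2)
        acc_tau[k] <- acc_tau[k] + 1
      }

      # spread move: rescale the k-th random-effect column together with
      # its SD (funnel traversal); hierarchical terms cancel against the
      # jacobian up to +log(c)
      lc <- step_spread[k] * stats::rnorm(1)
      cc <- exp(lc)
      d_u <- (cc - 1) * u[, k]
      d_row <- X[, k] * d_u[subj]
      r_cur <- y - fixed_row - u_row
      d_ll <- -(sum((r_cur - d_row)^2) - sum(r_cur^2)) / (2 * sig^2)
      log_alpha <- d_ll +
        .half_normal_lp(tau[k] * cc, 1) - .half_normal_lp(tau[k], 1) + lc
      if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
        u[, k] <- cc * u[, k]
        tau[k] <- tau[k] * cc
        u_row <- u_row + d_row
        acc_spread[k] <- acc_spread[k] + 1
      }
    }

    # sigma | rest
    SS <- sum((y - fixed_row - u_row)^2)
    ls <- log(sig)
    ls2 <- ls + step_sig * stats::rnorm(1)
    tgt <- function(l) {
      s <- exp(l)
      -n * l - SS / (2 * s^2) + .half_normal_lp(s, 1) + l
    }
    if (log(stats::runif(1)) < tgt(ls2) - tgt(ls)) {
      sig <- exp(ls2)
      acc_sig <- acc_sig + 1
    }

    if (iter <= config$tune && iter %% batch == 0) {
      adj <- function(step, acc) {
        step * exp(pmax(pmin(acc / batch - 0.44, 0.25), -0.25))
      }
      step_tau <- adj(step_tau, acc_tau); acc_tau <- numeric(P)
      step_spread <- adj(step_spread, acc_spread); acc_spread <- numeric(P)
      step_sig <- adj(step_sig, acc_sig); acc_sig <- 0
    }
    if (iter > config$tune) {
      draws[iter - config$tune, ] <- c(beta, tau, sig)
      ranef_mean <- ranef_mean + u / config$draws
    }
  }
  list(draws = draws, ranef_mean = ranef_mean)
}

#' Fit the learning-efficiency model for saccadic latencies
#'
#' Filters the gaze table per the specification (predictable-location
#' trials, first trial of each sequence excluded), standardises saccadic
#' latency, and fits the Bayesian mixed model by MCMC. Marginal effects of
#' sequence number are reported at each within-sequence trial index (with
#' the overall-trial covariate held at its mean).
#'
#' @param table A `gaze_table` containing saccadic latencies.
#' @param design The `task_design` behind the table.
#' @param spec An [efficiency_spec()].
#' @param config A [fit_config()] (default: 2 chains, 500 tune, 1000 draws).
#' @param hdi_mass HDI mass (default 0.94).
#' @return An `efficiency_fit` list: `summaries` (fixed effects),
#'   `marginal_effects` (effect of sequence number on standardised SL at
#'   each trial), `filter_log`, `draws`, `max_rhat`, `converged`.
#' @export
fit_efficiency_model <- function(table, design, spec = efficiency_spec(),
                                 config = fit_config(tune = 500L, draws = 1000L),
                                 hdi_mass = 0.94) {
  ed <- .efficiency_data(table, design, spec)
  chains <- lapply(seq_len(config$chains), function(ch) {
    .run_efficiency_chain(ed, config, ch)
  })
  pn <- colnames(chains[[1]]$draws)
  arr <- array(NA_real_, c(config$draws, config$chains, length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (ch in seq_along(chains)) arr[, ch, ] <- chains[[ch]]$draws

  rhat <- vapply(pn, function(p) split_rhat(arr[, , p]), numeric(1))
  ess <- vapply(pn, function(p) ess_mean(arr[, , p]), numeric(1))
  summaries <- dplyr::bind_rows(lapply(pn, function(p) {
    x <- as.vector(arr[, , p])
    h <- hdi(x, hdi_mass)
    tibble::tibble(parameter = p, mean = mean(x), sd = stats::sd(x),
                   hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
                   rhat = rhat[[p]], ess = ess[[p]],
                   nonzero = h[["lower"]] > 0 | h[["upper"]] < 0)
  }))

  # marginal effect of sequence number at each trial index
  b_seq <- as.vector(arr[, , "sequence"])
  b_int <- as.vector(arr[, , "sequence:log_trial"])
  trial_idx <- 2:design$n_trials
  me <- dplyr::bind_rows(lapply(trial_idx, function(t) {
    eff <- b_seq + b_int * (log(t) - ed$log_trial_centering)
    h <- hdi(eff, hdi_mass)
    tibble::tibble(trial = t, mean = mean(eff),
                   hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
                   nonzero = h[["lower"]] > 0 | h[["upper"]] < 0)
  }))

  max_rhat <- max(rhat, na.rm = TRUE)
  structure(
    list(summaries = summaries, marginal_effects = me,
         filter_log = ed$filter_log, n_used = ed$n_used, n_input = ed$n_input,
         draws = arr, max_rhat = max_rhat,
         converged = is.finite(max_rhat) && max_rhat < 1.05,
         config = config),
    class = "efficiency_fit"
  )
}

#' Simulate a cohort with a built-in learning-efficiency signature
#'
#' Takes the truncation/dropout structure from [simulate_cohort()] and
#' regenerates saccadic latencies directly from the efficiency model's own
#' generative form (fixed effects on centred sequence number, log trial
#' number, their interaction and overall trial number; per-infant random
#' intercepts and slopes; Gaussian noise). Used to validate that the
#' efficiency analysis detects within-sequence learning (negative log-trial
#' effect) and meta-learning (positive sequence-by-trial interaction:
#' faster early-trial latencies in later sequences).
#'
#' @param design A `task_design`.
#' @param coefs Named vector of generating fixed effects on the
#'   standardised SL scale: `intercept`, `sequence`, `log_trial`,
#'   `interaction`, `overall_trial`.
#' @param n_infants Number of infants (default 73).
#' @param ranef_sd Named vector of random-effect SDs (same order).
#' @param resid_sd Residual SD (standardised scale).
#' @param config A [cohort_config()] used for the truncation/dropout
#'   structure.
#' @param seed Integer seed.
#' @return A `gaze_table` whose saccadic latencies follow the efficiency
#'   generative model (on a 400 +/- 150 ms scale).
#' @export
simulate_efficiency_cohort <- function(design,
                                       coefs = c(intercept = 0, sequence = -0.02,
                                                 log_trial = -0.45,
                                                 interaction = 0.08,
                                                 overall_trial = -0.002),
                                       n_infants = 73L,
                                       ranef_sd = c(intercept = 0.3,
                                                    sequence = 0.02,
                                                    log_trial = 0.15,
                                                    interaction = 0.02,
                                                    overall_trial = 0.002),
                                       resid_sd = 1,
                                       config = cohort_config(n_infants = n_infants),
                                       seed = 1L) {
  g <- simulate_cohort(design, config, seed = seed)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed) + 1L)

  ids <- sort(unique(g$infant_id))
  J <- length(ids)
  u <- sapply(ranef_sd, function(s) stats::rnorm(J, 0, s))
  subj <- match(g$infant_id, ids)

  seqc <- g$sequence - mean(g$sequence)
  logtr <- log(g$trial) - mean(log(g$trial))
  overall <- (g$sequence - 1) * design$n_trials + g$trial
  overallc <- overall - mean(overall)
  X <- cbind(1, seqc, logtr, seqc * logtr, overallc)
  z <- drop(X %*% coefs) + rowSums(X * u[subj, , drop = FALSE]) +
    stats::rnorm(nrow(g), 0, resid_sd)
  g$saccadic_latency_ms <- ifelse(g$look_away == 1, NA_real_, 400 + 150 * z)
  g
}
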