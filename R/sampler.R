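# Blocked Gibbs / adaptive-Metropolis sampler for the joint observation
# model. Gaussian channels (saccadic latency, log looking time) use exact
# conjugate Gibbs draws for subject effects, covariate slopes and group
# means; the Bernoulli-logit look-away channel and the nonlinear weighting
# kernel use adaptive random-walk Metropolis. A multiplicative scale move
# rescales the kernel scale (la0, la1) against all IG coefficients jointly,
# traversing the kernel-scale/coefficient ridge that defeats
# one-parameter-at-a-time samplers.

.log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# per-infant sums robust to infants with no rows in a channel
.accum <- function(v, subj, J) {
  out <- numeric(J)
  if (length(v) == 0) return(out)
  tmp <- rowsum(v, subj)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

.ll_bern <- function(eta, y) y * eta - .log1pexp(eta)

.half_normal_lp <- function(x, scale) {
  ifelse(x < 0, -Inf, stats::dnorm(x, 0, scale, log = TRUE) + log(2))
}

.kernel_eval <- function(st, cells) {
  (st$la0 + st$la1 * cells$s) * exp(-cells$t * (st$ba0 + st$ba1 * cells$s)) *
    cells$dkl
}

# linear predictors for one channel given current state
.eta_channel <- function(st, d, ch, ig) {
  st[[d]]$a[ch$subj] + st[[d]]$b[ch$subj] * ig[ch$cell] +
    st[[d]]$cc * ch$tc + st[[d]]$dd * ch$sc
}

.init_state <- function(model, chain, seed) {
  set.seed(seed * 1000L + chain)
  dat <- model$data
  free <- model$variant$free_params
  ig0 <- .kernel_eval(list(la0 = 1, la1 = 0, ba0 = 0.1, ba1 = 0), dat$cells)
  jit <- function(x, s) x + stats::rnorm(1, 0, s)

  init_ch <- function(ch, binomial = FALSE) {
    x <- ig0[ch$cell]
    co <- tryCatch({
      if (binomial) {
        stats::coef(stats::glm(ch$y ~ x + ch$tc + ch$sc,
                               family = stats::binomial()))
      } else {
        stats::coef(stats::lm(ch$y ~ x + ch$tc + ch$sc))
      }
    }, error = function(e) c(0, 0, 0, 0))
    co[!is.finite(co)] <- 0
    mu_a <- jit(co[[1]], 0.2)
    mu_b <- jit(co[[2]], max(0.2, 0.2 * abs(co[[2]])))
    list(mu_a = mu_a, mu_b = mu_b,
         cc = jit(co[[3]], 0.02), dd = jit(co[[4]], 0.02),
         sd_a = 0.5 * exp(stats::rnorm(1, 0, 0.2)),
         sd_b = 0.5 * exp(stats::rnorm(1, 0, 0.2)),
         a = rep(mu_a, dat$J) + stats::rnorm(dat$J, 0, 0.05),
         b = rep(mu_b, dat$J) + stats::rnorm(dat$J, 0, 0.05))
  }
  # weighting start values must satisfy kernel validity over the design's
  # sequence range (la0 + la1*s > 0, ba0 + ba1*s >= 0), or the chain's
  # initial density is degenerate
  s_max <- max(dat$cells$s)
  la0_init <- exp(stats::rnorm(1, 0, 0.2))
  ba0_init <- 0.1 * exp(stats::rnorm(1, 0, 0.4))
  la1_init <- ba1_init <- 0
  if ("la1" %in% free) {
    repeat {
      la1_init <- stats::rnorm(1, 0, 0.01)
      if (la0_init + la1_init * s_max > 0) break
    }
  }
  if ("ba1" %in% free) {
    repeat {
      ba1_init <- stats::rnorm(1, 0, 0.005)
      if (ba0_init + ba1_init * s_max >= 0) break
    }
  }
  st <- list(
    la0 = la0_init,
    la1 = la1_init,
    ba0 = ba0_init,
    ba1 = ba1_init,
    la = init_ch(dat$la, binomial = TRUE),
    sl = init_ch(dat$sl),
    lt = init_ch(dat$lt),
    sig_sl = stats::sd(dat$sl$y) * exp(stats::rnorm(1, 0, 0.1)),
    sig_lt = stats::sd(dat$lt$y) * exp(stats::rnorm(1, 0, 0.1))
  )
  st
}

# one chain; returns draws matrix (draws x params) with named columns
.run_chain <- function(model, config, chain) {
  dat <- model$data
  pri <- model$priors
  J <- dat$J
  free_la1 <- "la1" %in% model$variant$free_params
  free_ba1 <- "ba1" %in% model$variant$free_params
  st <- .init_state(model, chain, config$seed)

  ig <- .kernel_eval(st, dat$cells)
  eta_la <- .eta_channel(st, "la", dat$la, ig)
  mu_sl <- .eta_channel(st, "sl", dat$sl, ig)
  mu_lt <- .eta_channel(st, "lt", dat$lt, ig)

  # adaptive scales
  step_a_la <- rep(0.3, J); step_b_la <- rep(0.6, J)
  acc_a_la <- acc_b_la <- numeric(J)
  step_c_la <- 0.05; step_d_la <- 0.05; acc_c_la <- acc_d_la <- 0
  step_sig <- c(sl = 0.05, lt = 0.05); acc_sig <- c(sl = 0, lt = 0)
  step_sd <- stats::setNames(rep(0.2, 6), c(
    "la.a", "la.b", "sl.a", "sl.b", "lt.a", "lt.b"))
  acc_sd <- step_sd * 0
  step_shift <- stats::setNames(rep(0.2, 6), names(step_sd))
  acc_shift <- step_shift * 0
  step_spread <- stats::setNames(rep(0.15, 6), names(step_sd))
  acc_spread <- step_spread * 0
  n_w <- 2L + free_la1 + free_ba1
  w_sd0 <- c(0.02, if (free_la1) 0.005 else NULL,
             0.02, if (free_ba1) 0.005 else NULL)
  cov_w <- diag(w_sd0^2, n_w)
  chol_w <- chol_w_fixed <- chol(cov_w * 2.38^2 / n_w)
  step_w <- 1
  acc_w <- 0; n_w_tries <- 0
  w_hist <- matrix(NA_real_, min(config$tune, 2000L), n_w)
  w_hist_n <- 0L
  step_scale_move <- 0.2
  acc_scale <- 0
  acc_w_post <- 0; tries_w_post <- 0; acc_scale_post <- 0

  ll_la_v <- .ll_bern(eta_la, dat$la$y)
  batch <- 50L

  # transformed weighting vector: log scale for the kernel scale la0
  # (lognormal prior, multiplicative parameter), natural scale for the
  # slopes and the decay intercept (their posterior correlation is linear;
  # the ba0 >= 0 boundary is handled by rejection). Kernel validity over
  # the design's sequence range is part of the support.
  s_max <- max(dat$cells$s)
  get_u <- function() {
    u <- log(st$la0)
    if (free_la1) u <- c(u, st$la1)
    u <- c(u, st$ba0)
    if (free_ba1) u <- c(u, st$ba1)
    u
  }
  set_u <- function(u) {
    s2 <- st
    i <- 1
    s2$la0 <- exp(u[i]); i <- i + 1
    if (free_la1) { s2$la1 <- u[i]; i <- i + 1 }
    s2$ba0 <- u[i]; i <- i + 1
    if (free_ba1) s2$ba1 <- u[i]
    s2
  }
  lp_w <- function(s2) {
    if (s2$ba0 < 0 ||
        s2$la0 + s2$la1 * (if (s2$la1 < 0) s_max else 1) <= 0 ||
        s2$ba0 + s2$ba1 * (if (s2$ba1 < 0) s_max else 1) < 0) {
      return(-Inf)
    }
    # prior in u-space: la0's lognormal becomes normal on log la0
    lp <- stats::dnorm(log(s2$la0), pri$la0_meanlog, pri$la0_sdlog, log = TRUE)
    if (free_la1) lp <- lp + stats::dnorm(s2$la1, 0, pri$la1_sd, log = TRUE)
    lp <- lp + .half_normal_lp(s2$ba0, pri$ba0_sd)
    if (free_ba1) lp <- lp + stats::dnorm(s2$ba1, 0, pri$ba1_sd, log = TRUE)
    lp
  }

  gauss_ll <- function(y, mu, sig) {
    -length(y) * log(sig) - sum((y - mu)^2) / (2 * sig^2)
  }

  n_iter <- config$tune + config$draws
  par_names <- c(
    "la0", "la1", "ba0", "ba1",
    unlist(lapply(c("la", "sl", "lt"), function(d) {
      paste0(c("mu_a_", "mu_b_", "c_", "d_", "sd_a_", "sd_b_"), d)
    })),
    "sig_sl", "sig_lt",
    unlist(lapply(c("la", "sl", "lt"), function(d) {
      c(paste0("a_", d, "[", seq_len(J), "]"),
        paste0("b_", d, "[", seq_len(J), "]"))
    }))
  )
  draws <- matrix(NA_real_, config$draws, length(par_names),
                  dimnames = list(NULL, par_names))

  for (iter in seq_len(n_iter)) {
    tuning <- iter <= config$tune

    ## -- weighting kernel block (adaptive MVN random walk) --
    ll_sl_cur <- gauss_ll(dat$sl$y, mu_sl, st$sig_sl)
    ll_lt_cur <- gauss_ll(dat$lt$y, mu_lt, st$sig_lt)
    for (rep in 1:8) {
      u <- get_u()
      # mixture kernel: mostly the adapted covariance, occasionally the
      # fixed-scale component (guards against adaptive collapse)
      up <- if (stats::runif(1) < 0.9) {
        u + step_w * drop(stats::rnorm(n_w) %*% chol_w)
      } else {
        u + drop(stats::rnorm(n_w) %*% chol_w_fixed)
      }
      s2 <- set_u(up)
      ig2 <- .kernel_eval(s2, dat$cells)
      eta2 <- eta_la + st$la$b[dat$la$subj] * (ig2 - ig)[dat$la$cell]
      mu_sl2 <- mu_sl + st$sl$b[dat$sl$subj] * (ig2 - ig)[dat$sl$cell]
      mu_lt2 <- mu_lt + st$lt$b[dat$lt$subj] * (ig2 - ig)[dat$lt$cell]
      ll_la2 <- .ll_bern(eta2, dat$la$y)
      ll_sl2 <- gauss_ll(dat$sl$y, mu_sl2, st$sig_sl)
      ll_lt2 <- gauss_ll(dat$lt$y, mu_lt2, st$sig_lt)
      d_ll <- sum(ll_la2) - sum(ll_la_v) + ll_sl2 - ll_sl_cur +
        ll_lt2 - ll_lt_cur
      log_alpha <- d_ll + lp_w(s2) - lp_w(st)
      n_w_tries <- n_w_tries + 1
      if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
        st <- s2; ig <- ig2; eta_la <- eta2; mu_sl <- mu_sl2; mu_lt <- mu_lt2
        ll_la_v <- ll_la2
        ll_sl_cur <- ll_sl2; ll_lt_cur <- ll_lt2
        acc_w <- acc_w + 1
        if (!tuning) acc_w_post <- acc_w_post + 1
      }
      if (!tuning) tries_w_post <- tries_w_post + 1
    }
    if (tuning) {
      w_hist_n <- w_hist_n + 1L
      w_hist[(w_hist_n - 1L) %% nrow(w_hist) + 1L, ] <- get_u()
    }

    ## -- scale move along the kernel-scale x coefficient ridge --
    lc <- stats::rnorm(1, 0, step_scale_move)
    cc_ <- exp(lc)
    # natural-space log prior densities (lognormal density includes -log x)
    lp_old <- stats::dnorm(log(st$la0), pri$la0_meanlog, pri$la0_sdlog, log = TRUE) -
      log(st$la0) +
      (if (free_la1) stats::dnorm(st$la1, 0, pri$la1_sd, log = TRUE) else 0)
    lp_new <- stats::dnorm(log(st$la0) + lc, pri$la0_meanlog, pri$la0_sdlog, log = TRUE) -
      (log(st$la0) + lc) +
      (if (free_la1) stats::dnorm(st$la1 * cc_, 0, pri$la1_sd, log = TRUE) else 0)
    for (d in c("la", "sl", "lt")) {
      lp_old <- lp_old +
        stats::dnorm(st[[d]]$mu_b, 0, pri$coef_sd, log = TRUE) +
        .half_normal_lp(st[[d]]$sd_b, pri$subject_sd_scale) +
        sum(stats::dnorm(st[[d]]$b, st[[d]]$mu_b, st[[d]]$sd_b, log = TRUE))
      lp_new <- lp_new +
        stats::dnorm(st[[d]]$mu_b / cc_, 0, pri$coef_sd, log = TRUE) +
        .half_normal_lp(st[[d]]$sd_b / cc_, pri$subject_sd_scale) +
        sum(stats::dnorm(st[[d]]$b / cc_, st[[d]]$mu_b / cc_,
                         st[[d]]$sd_b / cc_, log = TRUE))
    }
    n_mult <- 1 + free_la1
    n_div <- 3 * (2 + J)
    log_alpha <- lp_new - lp_old + (n_mult - n_div) * lc
    if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
      st$la0 <- st$la0 * cc_
      st$la1 <- st$la1 * cc_
      for (d in c("la", "sl", "lt")) {
        st[[d]]$mu_b <- st[[d]]$mu_b / cc_
        st[[d]]$sd_b <- st[[d]]$sd_b / cc_
        st[[d]]$b <- st[[d]]$b / cc_
      }
      ig <- .kernel_eval(st, dat$cells)
      eta_la <- .eta_channel(st, "la", dat$la, ig)
      mu_sl <- .eta_channel(st, "sl", dat$sl, ig)
      mu_lt <- .eta_channel(st, "lt", dat$lt, ig)
      ll_la_v <- .ll_bern(eta_la, dat$la$y)
      acc_scale <- acc_scale + 1
      if (!tuning) acc_scale_post <- acc_scale_post + 1
    }

    ## -- look-away channel (Metropolis) --
    x_la <- ig[dat$la$cell]
    for (what in c("a", "b")) {
      cur <- st$la[[what]]
      step <- if (what == "a") step_a_la else step_b_la
      prop <- cur + step * stats::rnorm(J)
      delta <- prop - cur
      d_eta <- if (what == "a") delta[dat$la$subj] else delta[dat$la$subj] * x_la
      ll2 <- .ll_bern(eta_la + d_eta, dat$la$y)
      d_ll_j <- .accum(ll2 - ll_la_v, dat$la$subj, J)
      mu0 <- if (what == "a") st$la$mu_a else st$la$mu_b
      sd0 <- if (what == "a") st$la$sd_a else st$la$sd_b
      d_pri <- stats::dnorm(prop, mu0, sd0, log = TRUE) -
        stats::dnorm(cur, mu0, sd0, log = TRUE)
      acc <- log(stats::runif(J)) < (d_ll_j + d_pri)
      if (any(acc)) {
        cur[acc] <- prop[acc]
        st$la[[what]] <- cur
        keep_delta <- delta * acc
        d_eta_acc <- if (what == "a") keep_delta[dat$la$subj] else
          keep_delta[dat$la$subj] * x_la
        eta_la <- eta_la + d_eta_acc
        ll_la_v <- .ll_bern(eta_la, dat$la$y)
      }
      if (what == "a") acc_a_la <- acc_a_la + acc else acc_b_la <- acc_b_la + acc
    }
    for (what in c("cc", "dd")) {
      cur <- st$la[[what]]
      step <- if (what == "cc") step_c_la else step_d_la
      prop <- cur + step * stats::rnorm(1)
      xv <- if (what == "cc") dat$la$tc else dat$la$sc
      ll2 <- .ll_bern(eta_la + (prop - cur) * xv, dat$la$y)
      log_alpha <- sum(ll2) - sum(ll_la_v) +
        stats::dnorm(prop, 0, pri$cov_sd, log = TRUE) -
        stats::dnorm(cur, 0, pri$cov_sd, log = TRUE)
      if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
        st$la[[what]] <- prop
        eta_la <- eta_la + (prop - cur) * xv
        ll_la_v <- ll2
        if (what == "cc") acc_c_la <- acc_c_la + 1 else acc_d_la <- acc_d_la + 1
      }
    }

    ## -- Gaussian channels (exact Gibbs) --
    for (d in c("sl", "lt")) {
      ch <- dat[[d]]
      sig <- if (d == "sl") st$sig_sl else st$sig_lt
      x <- ig[ch$cell]
      # subject (a_j, b_j): bivariate normal conditional
      yres <- ch$y - st[[d]]$cc * ch$tc - st[[d]]$dd * ch$sc
      S1 <- .accum(rep(1, length(x)), ch$subj, J)
      Sx <- .accum(x, ch$subj, J)
      Sxx <- .accum(x^2, ch$subj, J)
      Sy <- .accum(yres, ch$subj, J)
      Sxy <- .accum(x * yres, ch$subj, J)
      isig2 <- 1 / sig^2
      p11 <- S1 * isig2 + 1 / st[[d]]$sd_a^2
      p12 <- Sx * isig2
      p22 <- Sxx * isig2 + 1 / st[[d]]$sd_b^2
      h1 <- Sy * isig2 + st[[d]]$mu_a / st[[d]]$sd_a^2
      h2 <- Sxy * isig2 + st[[d]]$mu_b / st[[d]]$sd_b^2
      det <- p11 * p22 - p12^2
      m1 <- (p22 * h1 - p12 * h2) / det
      m2 <- (p11 * h2 - p12 * h1) / det
      L11 <- sqrt(p11)
      L21 <- p12 / L11
      L22 <- sqrt(pmax(p22 - L21^2, 1e-300))
      z1 <- stats::rnorm(J); z2 <- stats::rnorm(J)
      bb <- m2 + z2 / L22
      aa <- m1 + (z1 - L21 * (bb - m2)) / L11
      st[[d]]$a <- aa
      st[[d]]$b <- bb
      mu_d <- .eta_channel(st, d, ch, ig)

      # covariate slopes: scalar conjugate draws
      for (what in c("cc", "dd")) {
        xv <- if (what == "cc") ch$tc else ch$sc
        r <- ch$y - (mu_d - st[[d]][[what]] * xv)
        prec <- sum(xv^2) * isig2 + 1 / pri$cov_sd^2
        mean_ <- sum(xv * r) * isig2 / prec
        newv <- stats::rnorm(1, mean_, 1 / sqrt(prec))
        mu_d <- mu_d + (newv - st[[d]][[what]]) * xv
        st[[d]][[what]] <- newv
      }
      if (d == "sl") mu_sl <- mu_d else mu_lt <- mu_d

      # residual scale: random walk on log sigma
      SS <- sum((ch$y - mu_d)^2)
      nn <- length(ch$y)
      lsig <- log(sig)
      lsig2 <- lsig + step_sig[[d]] * stats::rnorm(1)
      target <- function(ls) {
        s <- exp(ls)
        -nn * ls - SS / (2 * s^2) + .half_normal_lp(s, pri$noise_sd_scale) + ls
      }
      if (log(stats::runif(1)) < target(lsig2) - target(lsig)) {
        sig <- exp(lsig2)
        acc_sig[[d]] <- acc_sig[[d]] + 1
      }
      if (d == "sl") st$sig_sl <- sig else st$sig_lt <- sig
    }

    ## -- hierarchy: group means (Gibbs) and deviation SDs (Metropolis) --
    for (d in c("la", "sl", "lt")) {
      for (what in c("a", "b")) {
        eff <- st[[d]][[what]]
        sd_ <- if (what == "a") st[[d]]$sd_a else st[[d]]$sd_b
        prec <- J / sd_^2 + 1 / pri$coef_sd^2
        mean_ <- sum(eff) / sd_^2 / prec
        mu_new <- stats::rnorm(1, mean_, 1 / sqrt(prec))
        if (what == "a") st[[d]]$mu_a <- mu_new else st[[d]]$mu_b <- mu_new

        mu_ <- mu_new
        key <- paste0(d, ".", what)
        lsd <- log(sd_)
        lsd2 <- lsd + step_sd[[key]] * stats::rnorm(1)
        tgt <- function(ls) {
          s <- exp(ls)
          sum(stats::dnorm(eff, mu_, s, log = TRUE)) +
            .half_normal_lp(s, pri$subject_sd_scale) + ls
        }
        if (log(stats::runif(1)) < tgt(lsd2) - tgt(lsd)) {
          if (what == "a") st[[d]]$sd_a <- exp(lsd2) else st[[d]]$sd_b <- exp(lsd2)
          acc_sd[[key]] <- acc_sd[[key]] + 1
        }
      }
    }

    ## -- translation moves: shift a group mean and all its subject
    ## -- effects jointly (the hierarchical density is invariant, so the
    ## -- move mixes the group mean at the marginal posterior scale) --
    for (d in c("la", "sl", "lt")) {
      ch <- dat[[d]]
      x_d <- ig[ch$cell]
      for (what in c("a", "b")) {
        key <- paste0(d, ".", what)
        delta <- step_shift[[key]] * stats::rnorm(1)
        d_eta <- if (what == "a") delta else delta * x_d
        mu_cur <- if (what == "a") st[[d]]$mu_a else st[[d]]$mu_b
        if (d == "la") {
          ll2 <- .ll_bern(eta_la + d_eta, dat$la$y)
          d_ll <- sum(ll2) - sum(ll_la_v)
        } else {
          mu_ch <- if (d == "sl") mu_sl else mu_lt
          sig <- if (d == "sl") st$sig_sl else st$sig_lt
          d_ll <- gauss_ll(ch$y, mu_ch + d_eta, sig) - gauss_ll(ch$y, mu_ch, sig)
        }
        log_alpha <- d_ll +
          stats::dnorm(mu_cur + delta, 0, pri$coef_sd, log = TRUE) -
          stats::dnorm(mu_cur, 0, pri$coef_sd, log = TRUE)
        if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
          if (what == "a") {
            st[[d]]$mu_a <- mu_cur + delta
            st[[d]]$a <- st[[d]]$a + delta
          } else {
            st[[d]]$mu_b <- mu_cur + delta
            st[[d]]$b <- st[[d]]$b + delta
          }
          if (d == "la") {
            eta_la <- eta_la + d_eta
            ll_la_v <- .ll_bern(eta_la, dat$la$y)
          } else if (d == "sl") {
            mu_sl <- mu_sl + d_eta
          } else {
            mu_lt <- mu_lt + d_eta
          }
          acc_shift[[key]] <- acc_shift[[key]] + 1
        }

        ## spread move: contract/expand the subject deviations together
        ## with their SD (funnel traversal); hierarchical density and
        ## jacobian contribute a net +log(c)
        lc2 <- step_spread[[key]] * stats::rnorm(1)
        cc2 <- exp(lc2)
        mu_now <- if (what == "a") st[[d]]$mu_a else st[[d]]$mu_b
        eff_now <- if (what == "a") st[[d]]$a else st[[d]]$b
        sd_now <- if (what == "a") st[[d]]$sd_a else st[[d]]$sd_b
        eff_new <- mu_now + cc2 * (eff_now - mu_now)
        d_eff <- eff_new - eff_now
        d_eta2 <- if (what == "a") d_eff[ch$subj] else d_eff[ch$subj] * x_d
        if (d == "la") {
          ll2 <- .ll_bern(eta_la + d_eta2, dat$la$y)
          d_ll2 <- sum(ll2) - sum(ll_la_v)
        } else {
          mu_ch <- if (d == "sl") mu_sl else mu_lt
          sig <- if (d == "sl") st$sig_sl else st$sig_lt
          d_ll2 <- gauss_ll(ch$y, mu_ch + d_eta2, sig) - gauss_ll(ch$y, mu_ch, sig)
        }
        log_alpha <- d_ll2 +
          .half_normal_lp(sd_now * cc2, pri$subject_sd_scale) -
          .half_normal_lp(sd_now, pri$subject_sd_scale) + lc2
        if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
          if (what == "a") {
            st[[d]]$a <- eff_new
            st[[d]]$sd_a <- sd_now * cc2
          } else {
            st[[d]]$b <- eff_new
            st[[d]]$sd_b <- sd_now * cc2
          }
          if (d == "la") {
            eta_la <- eta_la + d_eta2
            ll_la_v <- .ll_bern(eta_la, dat$la$y)
          } else if (d == "sl") {
            mu_sl <- mu_sl + d_eta2
          } else {
            mu_lt <- mu_lt + d_eta2
          }
          acc_spread[[key]] <- acc_spread[[key]] + 1
        }
      }
    }

    ## -- adaptation during warm-up --
    if (tuning && iter %% batch == 0) {
      adj <- function(step, acc, target) {
        step * exp(pmax(pmin((acc / batch - target), 0.25), -0.25))
      }
      step_a_la <- adj(step_a_la, acc_a_la, 0.44); acc_a_la <- numeric(J)
      step_b_la <- adj(step_b_la, acc_b_la, 0.44); acc_b_la <- numeric(J)
      step_c_la <- adj(step_c_la, acc_c_la, 0.44); acc_c_la <- 0
      step_d_la <- adj(step_d_la, acc_d_la, 0.44); acc_d_la <- 0
      step_sig <- adj(step_sig, acc_sig, 0.44); acc_sig[] <- 0
      step_sd <- adj(step_sd, acc_sd, 0.44); acc_sd[] <- 0
      step_shift <- adj(step_shift, acc_shift, 0.44); acc_shift[] <- 0
      step_spread <- adj(step_spread, acc_spread, 0.44); acc_spread[] <- 0
      step_w <- max(adj(step_w, acc_w / 8, 0.25), 0.2)
      acc_w <- 0
      step_scale_move <- adj(step_scale_move, acc_scale, 0.44)
      acc_scale <- 0
      hist_ok <- stats::complete.cases(w_hist)
      # discard the earliest third of available history (transient)
      if (sum(hist_ok) > 150 && n_w > 1) {
        rows <- which(hist_ok)
        rows <- rows[-seq_len(floor(length(rows) / 3))]
        emp <- stats::cov(w_hist[rows, , drop = FALSE])
        # floor each component's scale so adaptation can never collapse
        emp <- emp + diag(pmax(diag(emp) * 1e-4, (w_sd0 / 4)^2), n_w)
        ch_try <- tryCatch(chol(emp * 2.38^2 / n_w), error = function(e) NULL)
        if (!is.null(ch_try)) chol_w <- ch_try
      }
    }

    if (!tuning) {
      k <- iter - config$tune
      draws[k, ] <- c(
        st$la0, st$la1, st$ba0, st$ba1,
        unlist(lapply(c("la", "sl", "lt"), function(d) {
          c(st[[d]]$mu_a, st[[d]]$mu_b, st[[d]]$cc, st[[d]]$dd,
            st[[d]]$sd_a, st[[d]]$sd_b)
        })),
        st$sig_sl, st$sig_lt,
        unlist(lapply(c("la", "sl", "lt"), function(d) c(st[[d]]$a, st[[d]]$b)))
      )
    }
  }
  if (anyNA(draws)) {
    stop("sampler produced missing draws (sampler failure)", call. = FALSE)
  }
  list(draws = draws,
       accept = c(weight = acc_w_post / max(tries_w_post, 1),
                  scale = acc_scale_post / config$draws))
}

#' Fit the hierarchical observation model by MCMC
#'
#' Runs `config$chains` independent chains of a blocked
#' Gibbs/adaptive-Metropolis sampler (see the methods vignette), computes
#' split R-hat and effective sample size for every parameter, and flags
#' convergence when the maximum split R-hat is below 1.05.
#'
#' @param model A [build_model()] object.
#' @param config A [fit_config()].
#' @return A `gaze_fit` object: `draws` (array draws x chains x parameters),
#'   `diagnostics` (tibble: parameter, rhat, ess), `converged`,
#'   `max_rhat`, plus the model, config and data hash.
#' @export
fit <- function(model, config = fit_config()) {
  stopifnot(inherits(model, "gaze_model"), inherits(config, "fit_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  chains <- lapply(seq_len(config$chains), function(ch) {
    .run_chain(model, config, ch)
  })
  pn <- colnames(chains[[1]]$draws)
  arr <- array(NA_real_, c(config$draws, config$chains, length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (ch in seq_along(chains)) arr[, ch, ] <- chains[[ch]]$draws
  accept <- rowMeans(sapply(chains, function(x) x$accept))

  # fixed (clamped) parameters are excluded from convergence diagnostics
  clamped <- setdiff(c("la1", "ba1"), model$variant$free_params)
  diag_params <- setdiff(pn, clamped)
  rhat <- vapply(diag_params, function(p) split_rhat(arr[, , p]), numeric(1))
  ess <- vapply(diag_params, function(p) ess_mean(arr[, , p]), numeric(1))
  diagnostics <- tibble::tibble(parameter = diag_params, rhat = rhat, ess = ess)
  max_rhat <- max(rhat, na.rm = TRUE)

  structure(
    list(
      draws = arr,
      accept = accept,
      diagnostics = diagnostics,
      max_rhat = max_rhat,
      converged = is.finite(max_rhat) && max_rhat < 1.05,
      model = model,
      config = config,
      data_hash = model$data$data_hash,
      variant = model$variant$name
    ),
    class = "gaze_fit"
  )
}

#' @export
print.gaze_fit <- function(x, ...) {
  cat(sprintf(
    "<gaze_fit> variant '%s': %d chains x %d draws; max split R-hat %.3f (%s)\n",
    x$variant, x$config$chains, x$config$draws, x$max_rhat,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Flatten posterior draws of selected parameters
#'
#' @param fit A `gaze_fit`.
#' @param params Character vector of parameter names.
#' @return Matrix (total draws x parameters).
#' @export
posterior_draws <- function(fit, params = NULL) {
  pn <- dimnames(fit$draws)[[3]]
  if (is.null(params)) params <- pn
  missing <- setdiff(params, pn)
  if (length(missing) > 0) {
    stop("unknown parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- sapply(params, function(p) as.vector(fit$draws[, , p]))
  matrix(out, ncol = length(params), dimnames = list(NULL, params))
}

#' Summarise posterior parameters
#'
#' Mean, SD, 94% highest-density interval, split R-hat, effective sample
#' size, and a `nonzero` flag set when the HDI excludes zero.
#'
#' @param fit A `gaze_fit`.
#' @param params Parameters to summarise (default: the weighting kernel and
#'   group-level parameters).
#' @param hdi_mass HDI probability mass (default 0.94).
#' @return A tibble with one row per parameter.
#' @export
summarize_fit <- function(fit, params = NULL, hdi_mass = 0.94) {
  pn <- dimnames(fit$draws)[[3]]
  if (is.null(params)) {
    params <- grep("^(la0|la1|ba0|ba1|mu_|c_|d_|sd_|sig_)", pn, value = TRUE)
    clamped <- setdiff(c("la1", "ba1"), fit$model$variant$free_params)
    params <- setdiff(params, clamped)
  }
  missing <- setdiff(params, pn)
  if (length(missing) > 0) {
    stop("unknown parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(params, function(p) {
    x <- as.vector(fit$draws[, , p])
    h <- hdi(x, hdi_mass)
    tibble::tibble(
      parameter = p, mean = mean(x), sd = stats::sd(x),
      hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
      rhat = split_rhat(fit$draws[, , p]),
      ess = ess_mean(fit$draws[, , p]),
      nonzero = h[["lower"]] > 0 | h[["upper"]] < 0
    )
  })
  dplyr::bind_rows(rows)
}
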