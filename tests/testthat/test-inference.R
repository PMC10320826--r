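test_that("build_model exposes the variant's free parameters and likelihood bookkeeping", {
  g <- small_cohort()
  d <- ref_design()

  m_null <- build_model("null", g, d)
  expect_setequal(m_null$free_weighting, c("la0", "ba0"))
  m_full <- build_model("full", g, d)
  expect_setequal(m_full$free_weighting, c("la0", "la1", "ba0", "ba1"))
  m_dw <- build_model("downweight", g, d)
  expect_setequal(m_dw$free_weighting, c("la0", "ba0", "ba1"))

  # likelihood terms: every trial contributes to look-away; only
  # non-missing cells contribute to the Gaussian channels
  expect_equal(m_full$n_la, nrow(g))
  expect_equal(m_full$n_sl, sum(!is.na(g$saccadic_latency_ms)))
  expect_equal(m_full$n_lt, sum(!is.na(g$looking_time_ms)))
  expect_equal(m_full$n_sl, nrow(g) - sum(g$look_away))

  # table inconsistent with the design is rejected
  g_bad <- g
  g_bad$location <- ifelse(g_bad$location == 1L, 2L, 1L)
  expect_error(build_model("full", g_bad, d), "disagree")
})

test_that("fits are deterministic given seed and flag convergence from split R-hat", {
  g <- small_cohort()
  d <- ref_design()
  m <- build_model("downweight", g, d)
  cfg <- fit_config(chains = 2, tune = 150, draws = 120, seed = 42)
  f1 <- fit(m, cfg)
  f2 <- fit(m, cfg)
  expect_equal(f1$draws, f2$draws)
  expect_equal(summarize_fit(f1), summarize_fit(f2))
  expect_equal(f1$converged, f1$max_rhat < 1.05)
  # clamped upweight slope is excluded from diagnostics but stored at 0
  expect_true(all(f1$draws[, , "la1"] == 0))
  expect_false("la1" %in% f1$diagnostics$parameter)
})

test_that("a small fit converges and recovers coefficient signs", {
  f <- small_fit()
  expect_lt(f$max_rhat, 1.05)
  s <- summarize_fit(f, c("mu_b_la", "mu_b_sl"))
  expect_lt(s$mean[s$parameter == "mu_b_la"], 0)
  expect_gt(s$mean[s$parameter == "mu_b_sl"], 0)
})

test_that("summarize_fit flags parameters whose HDI excludes zero", {
  f <- small_fit()
  s <- summarize_fit(f, c("sig_sl", "la1"))
  expect_true(s$nonzero[s$parameter == "sig_sl"]) # a scale is never near 0
  expect_error(summarize_fit(f, "not_a_parameter"), "unknown parameter")
  expect_error(posterior_draws(f, "nope"), "unknown parameter")
})

test_that("posterior predictive replication is calibrated and handles 0 draws", {
  f <- small_fit()
  ppc <- posterior_predictive(f, ndraws = 150, seed = 2)
  obs_rate <- mean(ppc$observed_la)
  rep_rates <- rowMeans(ppc$la)
  # observed look-away rate within the replicated distribution
  expect_gt(obs_rate, quantile(rep_rates, 0.005))
  expect_lt(obs_rate, quantile(rep_rates, 0.995))
  # SL replications cover the observed mean and spread
  expect_gt(mean(ppc$observed_sl_ms), quantile(rowMeans(ppc$sl_ms), 0.005))
  expect_lt(mean(ppc$observed_sl_ms), quantile(rowMeans(ppc$sl_ms), 0.995))
  expect_true(all(ppc$lt_ms > 0))

  empty <- posterior_predictive(f, ndraws = 0)
  expect_equal(nrow(empty$la), 0)
  expect_equal(nrow(empty$sl_ms), 0)
})

test_that("fit archives round-trip through plain text", {
  f <- small_fit()
  dir <- withr::local_tempdir()
  write_fit_archive(f, dir)
  expect_true(all(file.exists(file.path(
    dir, c("posterior.csv", "sample_stats.csv", "metadata.json")))))
  a <- read_fit_archive(dir)
  expect_equal(a$draws, f$draws)
  expect_equal(a$max_rhat, f$max_rhat)
  expect_equal(a$data_hash, f$data_hash)
  expect_equal(summarize_fit(a, c("ba1", "mu_b_la")),
               summarize_fit(f, c("ba1", "mu_b_la")))
  # archives feed downstream analyses
  sim <- simulate_unseen_sequence(a, ref_design(), positions = c(1, 5))
  expect_equal(nrow(sim), 30)
  expect_error(read_fit_archive(withr::local_tempdir()), "not a fit archive")
})

test_that("comparisons demand a shared dataset and a null reference", {
  d <- ref_design()
  g1 <- small_cohort()
  g2 <- simulate_cohort(d, cohort_config(n_infants = 12), seed = 99)
  cfg <- fit_config(chains = 2, tune = 150, draws = 120, seed = 1)
  f1 <- fit(build_model("null", g1, d), cfg)
  f2 <- fit(build_model("full", g2, d), cfg)
  expect_error(compare_models(list(null = f1, full = f2)), "differing data")
  f3 <- fit(build_model("full", g1, d), cfg)
  expect_error(compare_models(list(a = f1, b = f3)), "null")
  ct <- compare_models(list(null = f1, full = f3), max_draws = 100)
  expect_s3_class(ct, "comparison_table")
  # per-DV entries sum to the totals
  for (v in c("null", "full")) {
    sub <- ct[ct$variant == v, ]
    expect_equal(sub$neg_elpd_loo[sub$dv == "Total"],
                 sum(sub$neg_elpd_loo[sub$dv != "Total"]), tolerance = 1e-8)
    expect_equal(sub$neg_elpd_waic[sub$dv == "Total"],
                 sum(sub$neg_elpd_waic[sub$dv != "Total"]), tolerance = 1e-8)
  }
  expect_equal(ct$delta_loo[ct$variant == "null"], rep(0, 4), tolerance = 1e-10)
})
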