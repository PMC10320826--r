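# minimal stand-in posterior with chosen kernel parameters
mock_kernel_fit <- function(la0 = 1, la1 = 0, ba0 = 0.1, ba1 = 0,
                            spread = 0, n = 200) {
  pn <- c("la0", "la1", "ba0", "ba1")
  arr <- array(NA_real_, c(n, 2, 4), dimnames = list(NULL, NULL, pn))
  set.seed(1)
  vals <- c(la0, la1, ba0, ba1)
  for (k in 1:4) {
    arr[, , k] <- vals[k] + if (spread > 0) rnorm(2 * n, 0, spread * max(abs(vals[k]), 0.01)) else 0
  }
  structure(list(draws = arr, variant = "full",
                 model = list(variant = make_variant("full"))),
            class = "gaze_fit")
}

test_that("unseen-sequence simulation shows downweighting and degenerates correctly", {
  d <- ref_design()

  # pure downweighting, point-mass posterior
  f <- mock_kernel_fit(la0 = 1, la1 = 0, ba0 = 0.1, ba1 = 0.065)
  sim <- simulate_unseen_sequence(f, d, positions = c(1, 5), sequence = 16)
  c1 <- sim[sim$position == 1, ]
  c5 <- sim[sim$position == 5, ]
  expect_equal(nrow(c1), 15)
  # later position never higher, strictly lower everywhere (ba1 > 0)
  expect_true(all(c5$ig_mean < c1$ig_mean))
  # relative gap grows with trial: near-equality is closest at trial 1
  gap <- c5$ig_mean / c1$ig_mean
  expect_true(all(diff(gap) < 0))
  expect_equal(gap[1], exp(-4 * 0.065), tolerance = 1e-10)
  # point-mass posterior gives zero-width bands
  expect_equal(sim$band_lower, sim$ig_mean, tolerance = 1e-12)
  expect_equal(sim$band_upper, sim$ig_mean, tolerance = 1e-12)

  # no weighting slopes: positions indistinguishable
  f0 <- mock_kernel_fit(la0 = 1, la1 = 0, ba0 = 0.1, ba1 = 0)
  sim0 <- simulate_unseen_sequence(f0, d, positions = c(1, 5))
  expect_equal(sim0$ig_mean[sim0$position == 1],
               sim0$ig_mean[sim0$position == 5])

  # bands have positive width for a dispersed posterior
  fsp <- mock_kernel_fit(la0 = 1, la1 = 0, ba0 = 0.1, ba1 = 0.065, spread = 0.2)
  simsp <- simulate_unseen_sequence(fsp, d, positions = 5)
  expect_true(all(simsp$band_upper > simsp$band_lower))

  expect_error(simulate_unseen_sequence(f, d, positions = c(0, 5)), "1..16")
  expect_error(simulate_unseen_sequence(f, d, positions = 17), "1..16")
  expect_error(simulate_unseen_sequence(f, d, sequence = 42), "not in the design")
})

test_that("report bundle writes artifacts, marks absences, and is reproducible", {
  d <- ref_design()
  f <- small_fit()
  sim <- simulate_unseen_sequence(f, d)
  ppc <- posterior_predictive(f, ndraws = 20, seed = 1)

  dir_full <- withr::local_tempdir()
  out <- make_report(dir_full, fit = f, simulation = sim, ppc = ppc)
  expect_true(file.exists(out$manifest_path))
  for (a in out$artifacts) expect_true(file.exists(file.path(dir_full, a)))
  manifest <- jsonlite::read_json(out$manifest_path)
  expect_setequal(unlist(manifest$artifacts), sort(out$artifacts))

  # missing comparison input -> partial bundle, panel marked absent
  expect_equal(out$status, "partial")
  expect_true("model_comparison.csv" %in% out$absent)

  # rerun: manifest identical except the timestamp
  dir2 <- withr::local_tempdir()
  out2 <- make_report(dir2, fit = f, simulation = sim, ppc = ppc)
  m1 <- jsonlite::read_json(out$manifest_path)
  m2 <- jsonlite::read_json(out2$manifest_path)
  m1$timestamp <- m2$timestamp <- NULL
  expect_identical(m1, m2)

  # unwritable directory errors
  ro <- withr::local_tempdir()
  Sys.chmod(ro, "0500")
  if (file.access(ro, 2) != 0) {
    expect_error(make_report(file.path(ro, "x")), "cannot create|not writable")
  }
  Sys.chmod(ro, "0700")
})
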