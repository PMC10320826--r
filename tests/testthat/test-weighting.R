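test_that("identity kernel leaves the information trace unchanged", {
  tr <- info_trace(ref_design())
  w <- weight_info(tr, weighting_params(la0 = 1, la1 = 0, ba0 = 0, ba1 = 0))
  expect_equal(w$ig_weighted, w$d_kl)
})

test_that("kernel matches its closed form", {
  # pure downweighting: ratio of IG across sequence positions at fixed t
  p <- weighting_params(la0 = 1, la1 = 0, ba0 = 0.3, ba1 = 0.065)
  ratio <- weighting_kernel(5, 10, p) / weighting_kernel(1, 10, p)
  expect_equal(ratio, exp(-4 * 10 * 0.065), tolerance = 1e-12)
  expect_equal(ratio, 0.0743, tolerance = 1e-3)

  set.seed(4)
  for (i in 1:50) {
    pp <- weighting_params(la0 = runif(1, 0.5, 3), la1 = runif(1, 0, 0.2),
                           ba0 = runif(1, 0, 0.5), ba1 = runif(1, 0, 0.1))
    s <- sample(1:16, 1); t <- sample(1:15, 1)
    expect_equal(weighting_kernel(s, t, pp),
                 (pp$la0 + pp$la1 * s) * exp(-t * (pp$ba0 + pp$ba1 * s)))
  }
})

test_that("weighted IG is monotone in the expected directions", {
  tr <- info_trace(ref_design())
  # downweighting only: IG strictly decreasing in s at fixed t
  w <- weight_info(tr, weighting_params(la0 = 1, la1 = 0, ba0 = 0.1, ba1 = 0.05))
  k <- weighting_kernel(1:16, 5, weighting_params(la0 = 1, la1 = 0,
                                                  ba0 = 0.1, ba1 = 0.05))
  expect_true(all(diff(k) < 0))

  # upweighting only: kernel strictly increasing in s at every t
  up <- weighting_params(la0 = 1, la1 = 0.1, ba0 = 0.1, ba1 = 0)
  for (t in c(1, 7, 15)) {
    expect_true(all(diff(weighting_kernel(1:16, t, up)) > 0))
  }

  # no slopes: kernel constant across sequences
  flat <- weighting_params(la0 = 2, la1 = 0, ba0 = 0.2, ba1 = 0)
  expect_equal(weighting_kernel(1, 4, flat), weighting_kernel(16, 4, flat))

  # linearity in d_kl
  w1 <- weight_info(tr, up)
  tr2 <- tr; tr2$d_kl <- 3 * tr$d_kl
  w2 <- weight_info(tr2, up)
  expect_equal(w2$ig_weighted, 3 * w1$ig_weighted)

  # zero propagation
  expect_true(all((w1$ig_weighted == 0) == (tr$d_kl == 0)))
})

test_that("invalid weighting parameters are rejected with the offending index", {
  tr <- info_trace(ref_design())
  expect_error(weighting_params(la0 = -1), "la0")
  expect_error(weighting_params(ba0 = -0.1), "ba0")
  # valid at construction but invalid over the sequence range
  p <- weighting_params(la0 = 1, la1 = -0.2, ba0 = 0.1, ba1 = 0)
  expect_error(weight_info(tr, p), "sequence 5")
  p2 <- weighting_params(la0 = 1, la1 = 0, ba0 = 0.1, ba1 = -0.05)
  expect_error(weight_info(tr, p2), "sequence 3")
})

test_that("model variants clamp the right parameters", {
  shared <- weighting_params(la0 = 2, la1 = 0.1, ba0 = 0.2, ba1 = 0.05)
  v <- make_variant("null", shared)
  expect_equal(v$params$la1, 0)
  expect_equal(v$params$ba1, 0)
  expect_length(v$free_params, 0)

  v <- make_variant("upweight", shared)
  expect_equal(v$free_params, "la1")
  expect_equal(v$params$la1, 0.1)
  expect_equal(v$params$ba1, 0)

  v <- make_variant("downweight", shared)
  expect_equal(v$free_params, "ba1")
  expect_equal(v$params$la1, 0)
  expect_equal(v$params$ba1, 0.05)

  v <- make_variant("full", shared)
  expect_setequal(v$free_params, c("la1", "ba1"))

  expect_error(make_variant("bogus"), "unknown model variant")
})
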