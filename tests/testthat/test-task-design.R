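test_that("default design satisfies all structural invariants across seeds", {
  for (seed in c(1, 2, 17, 99, 12345)) {
    d <- generate_task_design(seed = seed)
    expect_length(validate_design(d), 0)
    expect_equal(nrow(d$sequences), 16)
    expect_equal(nrow(d$trials), 16 * 15)
    # schedule 6/6/4 with exact within-sequence counts
    expect_equal(sort(table(d$sequences$high_prob)),
                 sort(c(`0.6` = 6L, `0.8` = 6L, `1` = 4L)),
                 ignore_attr = TRUE)
    counts <- sapply(d$sequences$sequence, function(s) {
      sum(d$trials$location[d$trials$sequence == s] ==
            d$sequences$high_location[d$sequences$sequence == s])
    })
    expect_equal(counts, round(d$sequences$high_prob * 15))
    expect_true(all(counts %in% c(9L, 12L, 15L)))
    # exact 25% marginal per location
    expect_equal(unname(tabulate(d$trials$location, 4)), rep(60L, 4))
  }
})

test_that("the first sequence is fully predictable", {
  for (seed in 1:10) {
    d <- generate_task_design(seed = seed)
    expect_equal(d$sequences$high_prob[1], 1.0)
  }
})

test_that("probabilistic sequences use at least two distinct low-probability locations", {
  for (seed in 1:20) {
    d <- generate_task_design(seed = seed)
    for (s in d$sequences$sequence) {
      hp <- d$sequences$high_prob[s]
      if (hp < 1) {
        hl <- d$sequences$high_location[s]
        off <- d$trials$location[d$trials$sequence == s]
        off <- off[off != hl]
        expect_gte(length(unique(off)), 2)
      }
    }
  }
})

test_that("identical seeds give identical designs, different seeds differ", {
  d1 <- generate_task_design(seed = 7)
  d2 <- generate_task_design(seed = 7)
  d3 <- generate_task_design(seed = 8)
  expect_identical(d1$trials, d2$trials)
  expect_false(identical(d1$trials, d3$trials))
})

test_that("custom schedules work when feasible and error when not", {
  d <- generate_task_design(seed = 2, schedule = list(c(1.00, 4)))
  expect_length(validate_design(d), 0)
  expect_equal(unname(tabulate(d$trials$location, 4)), rep(15L, 4))

  # 70% of 15 trials is not an integer count
  expect_error(generate_task_design(seed = 1, schedule = list(c(0.7, 4))),
               "integer")
  # 3 sequences x 15 trials = 45 does not divide over 4 locations
  expect_error(generate_task_design(seed = 1, schedule = list(c(1.00, 3))),
               "25%|divide", ignore.case = TRUE)
})

test_that("validate_design reports specific violations", {
  d <- generate_task_design(seed = 1)
  expect_length(validate_design(d), 0)

  # corrupt a 60% sequence to have 10 high-location trials
  bad <- d
  s60 <- bad$sequences$sequence[bad$sequences$high_prob == 0.6][1]
  hl <- bad$sequences$high_location[bad$sequences$sequence == s60]
  rows <- which(bad$trials$sequence == s60 & bad$trials$location != hl)
  bad$trials$location[rows[1]] <- hl
  v <- validate_design(bad)
  expect_true(any(grepl(paste("sequence", s60), v) & grepl("high-likelihood", v)))

  # collapse all off-trials of a 60% sequence onto one location
  bad2 <- d
  other <- setdiff(1:4, hl)[1]
  rows <- which(bad2$trials$sequence == s60 & bad2$trials$location != hl)
  bad2$trials$location[rows] <- other
  v2 <- validate_design(bad2)
  expect_true(any(grepl("distinct low-probability", v2)))
})

test_that("design round-trips through its delimited text form", {
  d <- generate_task_design(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(d2$trials$location, d$trials$location)
  expect_equal(d2$sequences$high_location, d$sequences$high_location)
  expect_equal(d2$sequences$high_prob, d$sequences$high_prob)
  expect_length(validate_design(d2), 0)

  expect_error(read_design({
    p <- withr::local_tempfile(fileext = ".csv")
    readr::write_csv(tibble::tibble(a = 1), p)
    p
  }), "missing column")
})
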