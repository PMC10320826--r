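test_that("simulated cohorts are deterministic given seed and config", {
  d <- ref_design()
  cfg <- cohort_config(n_infants = 15)
  g1 <- simulate_cohort(d, cfg, seed = 4)
  g2 <- simulate_cohort(d, cfg, seed = 4)
  g3 <- simulate_cohort(d, cfg, seed = 5)
  expect_equal(as.data.frame(g1), as.data.frame(g2))
  expect_false(identical(g1$look_away, g3$look_away))
})

test_that("look-away truncates sequences and masks the gaze measures", {
  g <- small_cohort()
  grp <- split(g, paste(g$infant_id, g$sequence))
  for (rows in grp) {
    rows <- rows[order(rows$trial), ]
    expect_equal(rows$trial, seq_len(nrow(rows))) # contiguous from trial 1
    la_pos <- which(rows$look_away == 1)
    if (length(la_pos) > 0) {
      expect_length(la_pos, 1)
      expect_equal(la_pos, nrow(rows)) # nothing after the look-away
      expect_true(is.na(rows$saccadic_latency_ms[la_pos]))
      expect_true(is.na(rows$looking_time_ms[la_pos]))
    }
    expect_true(all(!is.na(rows$saccadic_latency_ms[rows$look_away == 0])))
  }
  expect_true(all(g$looking_time_ms[g$look_away == 0] > 0))
  # locations consistent with the design
  key <- paste(g$sequence, g$trial)
  dkey <- paste(ref_design()$trials$sequence, ref_design()$trials$trial)
  expect_equal(g$location,
               ref_design()$trials$location[match(key, dkey)])
})

test_that("dropout calibration puts mean sequences watched near the target", {
  h <- calibrate_dropout(target = 7, n_sequences = 16)
  # closed form check: E[min(G, 16)] = (1 - (1-h)^16)/h
  expect_equal((1 - (1 - h)^16) / h, 7, tolerance = 1e-9)

  d <- ref_design()
  means <- sapply(1:20, function(k) {
    mean(sequences_watched(simulate_cohort(d, cohort_config(), seed = 500 + k))$n_sequences)
  })
  expect_equal(mean(means), 7, tolerance = 0.5)
})

test_that("IG coefficients switched off remove the dependence on information gain", {
  d <- ref_design()
  cfg <- cohort_config(
    n_infants = 150,
    dv_coefficients = c(la = 0, sl = 0, lt = 0),
    trial_slopes = c(la = 0, sl = 0, lt = 0),
    attention_slopes = c(la = 0, sl = 0, lt = 0)
  )
  g <- simulate_cohort(d, cfg, seed = 9)
  tr <- weight_info(info_trace(d), cfg$weighting)
  key <- paste(g$sequence, g$trial)
  ig <- tr$ig_weighted[match(key, paste(tr$sequence, tr$trial))]
  ok <- !is.na(g$saccadic_latency_ms)
  slope <- stats::coef(stats::lm(g$saccadic_latency_ms[ok] ~ ig[ok]))[2]
  # on the raw ms scale (sd 150); slope indistinguishable from 0
  se <- summary(stats::lm(g$saccadic_latency_ms[ok] ~ ig[ok]))$coefficients[2, 2]
  expect_lt(abs(slope), 3 * se)
})

test_that("downweighting plus look-away IG effect yields earlier truncation in later sequences", {
  d <- ref_design()
  g <- simulate_cohort(d, cohort_config(n_infants = 400), seed = 13)
  trials_per_seq <- tapply(g$trial, list(g$infant_id, g$sequence), max)
  by_seq <- colMeans(trials_per_seq, na.rm = TRUE)
  early <- mean(by_seq[1:4]); late <- mean(by_seq[9:16], na.rm = TRUE)
  expect_gt(early, late)
})

test_that("exclusion rule drops infants below 20 trials and keeps the boundary", {
  g <- small_cohort()
  counts <- table(g$infant_id)
  # craft a table with exactly 19, 20 and 21 trials for three infants
  base <- g[g$infant_id == as.integer(names(counts)[1]), ]
  base <- base[order(base$sequence, base$trial), ]
  stopifnot(nrow(base) >= 21)
  mk <- function(id, n) {
    out <- base[seq_len(n), ]
    out$infant_id <- id
    # make the final kept row a clean non-lookaway row
    out$look_away[nrow(out)] <- 0L
    out$saccadic_latency_ms[nrow(out)] <- 300
    out$looking_time_ms[nrow(out)] <- 1000
    out
  }
  tab <- gazemeta:::as_gaze_table(dplyr::bind_rows(mk(1L, 19), mk(2L, 20), mk(3L, 21)))
  kept <- apply_exclusion(tab)
  expect_setequal(unique(kept$infant_id), c(2L, 3L))
  expect_equal(attr(kept, "n_excluded"), 1L)

  all_kept <- apply_exclusion(kept)
  expect_equal(nrow(all_kept), nrow(kept))
  expect_equal(attr(all_kept, "n_excluded"), 0L)
})

test_that("gaze tables round-trip through delimited text and invalid files are rejected", {
  g <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_table(g, path)
  g2 <- read_gaze_table(path)
  for (col in c("infant_id", "sequence", "trial", "location", "look_away")) {
    expect_equal(g2[[col]], g[[col]])
  }
  expect_equal(g2$saccadic_latency_ms, g$saccadic_latency_ms)
  expect_equal(g2$looking_time_ms, g$looking_time_ms)

  # header-only file -> empty valid table
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("infant_id", "sequence", "trial", "location", "look_away",
                   "saccadic_latency_ms", "looking_time_ms", sep = ","), p2)
  empty <- read_gaze_table(p2)
  expect_s3_class(empty, "gaze_table")
  expect_equal(nrow(empty), 0)

  # record after a look-away is a parse-time invariant violation
  p3 <- withr::local_tempfile(fileext = ".csv")
  bad <- tibble::tibble(
    infant_id = c(1L, 1L), sequence = c(1L, 1L), trial = c(1L, 2L),
    location = c(1L, 1L), look_away = c(1L, 0L),
    saccadic_latency_ms = c(NA, 300), looking_time_ms = c(NA, 900))
  readr::write_csv(bad, p3, na = "")
  expect_error(read_gaze_table(p3), "after a look-away")

  # missing column named in the error
  p4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad[, -7], p4, na = "")
  expect_error(read_gaze_table(p4), "looking_time_ms")
})
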