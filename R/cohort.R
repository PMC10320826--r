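#' Configuration for the synthetic gaze cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a cohort of infants watching the probabilistic cue-target task, with
#' (i) per-trial look-away (Bernoulli-logit) that truncates the sequence,
#' (ii) saccadic latency (Gaussian on a standardised scale, reported in ms;
#' negative values are anticipations), (iii) looking time (Gaussian on
#' log-ms, so always positive), all with means shifted linearly by the
#' weighted information gain, a trial-number covariate and a baseline
#' attention drift over sequences, and (iv) session dropout via a
#' per-sequence geometric hazard calibrated so infants watch 7 sequences
#' on average.
#'
#' DV coefficient defaults are the group-level posterior means reported for
#' the infant cohort (look-away -4.98, saccadic latency 0.69, looking time
#' -0.57 per unit of weighted information gain); the weighting defaults
#' carry the estimated down-weighting slope (`ba1 = 0.065`) and no
#' up-weighting. The kernel scale (`la0 = 8`) sets the dynamic range of the
#' weighted-IG regressor; it is calibrated so that the posterior
#' uncertainties of the DV coefficients in a simulated cohort match the
#' study's reported posterior SDs (see the methods vignette). Only the
#' product of kernel scale and DV coefficients is identified, so this
#' choice fixes the simulation's effect sizes, not its substantive
#' conclusions.
#'
#' @param n_infants Number of infants (default 73).
#' @param seed Integer seed (default 1).
#' @param weighting A [weighting_params()] object.
#' @param dv_coefficients Named vector `c(la=, sl=, lt=)`: effect of weighted
#'   IG on the look-away logit and on the standardised SL / log-LT scales.
#' @param trial_slopes Named vector: per-trial covariate slope per DV
#'   (trial centred at 8).
#' @param attention_slopes Named vector: baseline drift per sequence per DV
#'   (sequence centred at 8.5).
#' @param sl_location,sl_scale Saccadic-latency location (ms) and scale
#'   (ms per standardised unit).
#' @param lt_meanlog,lt_sdlog Looking-time location and scale on log-ms.
#' @param lookaway_base_logit Baseline look-away logit per trial.
#' @param subject_sd Named vector: between-infant SD of the IG coefficients
#'   `c(la=, sl=, lt=)`.
#' @param intercept_sd Named vector: between-infant SD of the DV baselines
#'   (logit / standardised units).
#' @param dropout_hazard Per-sequence probability of ending the session;
#'   `NULL` (default) calibrates it with [calibrate_dropout()] so the mean
#'   number of sequences watched is `target_sequences`.
#' @param target_sequences Calibration target for the dropout hazard.
#' @return A `cohort_config` object (named list, with the resolved hazard).
#' @export
cohort_config <- function(n_infants = 73L,
                          seed = 1L,
                          weighting = weighting_params(la0 = 8, la1 = 0,
                                                       ba0 = 0.1, ba1 = 0.065),
                          dv_coefficients = c(la = -4.98, sl = 0.69, lt = -0.57),
                          trial_slopes = c(la = 0.05, sl = -0.01, lt = -0.02),
                          attention_slopes = c(la = 0.05, sl = 0.01, lt = -0.02),
                          sl_location = 400, sl_scale = 150,
                          lt_meanlog = log(1500), lt_sdlog = 0.4,
                          lookaway_base_logit = -2.9,
                          subject_sd = c(la = 1.0, sl = 0.3, lt = 0.3),
                          intercept_sd = c(la = 0.5, sl = 0.3, lt = 0.3),
                          dropout_hazard = NULL,
                          target_sequences = 7) {
  stopifnot(n_infants >= 2, sl_scale > 0, lt_sdlog > 0,
            all(subject_sd > 0), all(intercept_sd > 0))
  for (v in list(dv_coefficients, trial_slopes, attention_slopes,
                 subject_sd, intercept_sd)) {
    stopifnot(all(c("la", "sl", "lt") %in% names(v)))
  }
  if (is.null(dropout_hazard)) {
    dropout_hazard <- calibrate_dropout(target_sequences)
  }
  stopifnot(dropout_hazard > 0, dropout_hazard < 1)
  structure(
    list(
      n_infants = as.integer(n_infants), seed = as.integer(seed),
      weighting = weighting, dv_coefficients = dv_coefficients,
      trial_slopes = trial_slopes, attention_slopes = attention_slopes,
      sl_location = sl_location, sl_scale = sl_scale,
      lt_meanlog = lt_meanlog, lt_sdlog = lt_sdlog,
      lookaway_base_logit = lookaway_base_logit,
      subject_sd = subject_sd, intercept_sd = intercept_sd,
      dropout_hazard = dropout_hazard,
      target_sequences = target_sequences
    ),
    class = "cohort_config"
  )
}

#' Calibrate the per-sequence session-dropout hazard
#'
#' Solves `E[min(G, n_sequences)] = target` for the hazard of a geometric
#' stopping process `G` (an infant always watches sequence 1 and continues
#' after each sequence with probability `1 - hazard`), so that the mean
#' number of sequences watched matches the target.
#'
#' @param target Mean sequences watched (default 7).
#' @param n_sequences Total sequences available (default 16).
#' @return The hazard, a probability in (0, 1).
#' @export
calibrate_dropout <- function(target = 7, n_sequences = 16L) {
  stopifnot(target > 1, target < n_sequences)
  f <- function(h) (1 - (1 - h)^n_sequences) / h - target
  stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}

.center_trial <- function(t) t - 8
.center_seq <- function(s) s - 8.5

#' Simulate a synthetic infant cohort on a task design
#'
#' Per infant, subject-level DV coefficients and baselines are drawn around
#' the group values; the session stops after a geometric number of
#' sequences; within each watched sequence, trials proceed until the first
#' look-away (which truncates the sequence: the look-away trial itself has
#' no saccadic latency or looking time, and no later trials exist).
#'
#' @param design A `task_design`.
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`. Identical seed and
#'   config give identical tables.
#' @return A `gaze_table`: a tibble with columns `infant_id`, `sequence`,
#'   `trial`, `location`, `look_away`, `saccadic_latency_ms`,
#'   `looking_time_ms` and attributes `seed`, `config_hash`, `design_seed`.
#' @export
#' @examples
#' d <- generate_task_design(seed = 1)
#' g <- simulate_cohort(d, cohort_config(n_infants = 10), seed = 2)
simulate_cohort <- function(design, config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(design, "task_design"), inherits(config, "cohort_config"))
  viol <- validate_design(design)
  if (length(viol) > 0) {
    stop("design does not validate: ", viol[1], call. = FALSE)
  }

  trace <- weight_info(info_trace(design), config$weighting)
  n_seq <- nrow(design$sequences)
  n_tr <- design$n_trials
  ig <- matrix(NA_real_, n_seq, n_tr)
  ig[cbind(trace$sequence, trace$trial)] <- trace$ig_weighted

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  n <- config$n_infants
  # subject-level parameters (group mean + between-infant deviation)
  b_la <- stats::rnorm(n, config$dv_coefficients[["la"]], config$subject_sd[["la"]])
  b_sl <- stats::rnorm(n, config$dv_coefficients[["sl"]], config$subject_sd[["sl"]])
  b_lt <- stats::rnorm(n, config$dv_coefficients[["lt"]], config$subject_sd[["lt"]])
  a_la <- stats::rnorm(n, config$lookaway_base_logit, config$intercept_sd[["la"]])
  a_sl <- stats::rnorm(n, 0, config$intercept_sd[["sl"]])
  a_lt <- stats::rnorm(n, 0, config$intercept_sd[["lt"]])
  n_watched <- pmin(1L + stats::rgeom(n, config$dropout_hazard), n_seq)

  # full grid of potentially-watched trials, truncated after the draws
  grid <- tidyr::expand_grid(infant_id = seq_len(n), sequence = seq_len(n_seq),
                             trial = seq_len(n_tr))
  grid <- grid[grid$sequence <= n_watched[grid$infant_id], ]
  i <- grid$infant_id
  s <- grid$sequence
  t <- grid$trial
  igv <- ig[cbind(s, t)]
  tc <- .center_trial(t)
  sc <- .center_seq(s)

  eta_la <- a_la[i] + b_la[i] * igv +
    config$trial_slopes[["la"]] * tc + config$attention_slopes[["la"]] * sc
  la <- as.integer(stats::runif(nrow(grid)) < stats::plogis(eta_la))

  z_sl <- a_sl[i] + b_sl[i] * igv +
    config$trial_slopes[["sl"]] * tc + config$attention_slopes[["sl"]] * sc +
    stats::rnorm(nrow(grid))
  z_lt <- a_lt[i] + b_lt[i] * igv +
    config$trial_slopes[["lt"]] * tc + config$attention_slopes[["lt"]] * sc +
    stats::rnorm(nrow(grid))

  # truncate each (infant, sequence) at its first look-away
  g <- (i - 1) * n_seq + s
  csum <- stats::ave(la, g, FUN = cumsum)
  keep <- (csum - la) == 0   # rows up to and including the first look-away

  out <- tibble::tibble(
    infant_id = i[keep],
    sequence = s[keep],
    trial = t[keep],
    location = design$trials$location[match(
      paste(s[keep], t[keep]), paste(design$trials$sequence, design$trials$trial))],
    look_away = la[keep],
    saccadic_latency_ms = ifelse(
      la[keep] == 1, NA_real_,
      config$sl_location + config$sl_scale * z_sl[keep]),
    looking_time_ms = ifelse(
      la[keep] == 1, NA_real_,
      exp(config$lt_meanlog + config$lt_sdlog * z_lt[keep]))
  )
  as_gaze_table(out, seed = as.integer(seed),
                config_hash = rlang::hash(config),
                design_seed = design$seed)
}

as_gaze_table <- function(df, seed = NA_integer_, config_hash = NA_character_,
                          design_seed = NA_integer_, n_excluded = 0L) {
  attr(df, "seed") <- seed
  attr(df, "config_hash") <- config_hash
  attr(df, "design_seed") <- design_seed
  attr(df, "n_excluded") <- n_excluded
  class(df) <- unique(c("gaze_table", class(df)))
  df
}

#' Number of sequences watched per infant
#'
#' A sequence counts as watched if the infant has at least one trial record
#' for it.
#'
#' @param table A `gaze_table`.
#' @return A tibble with columns `infant_id`, `n_sequences`.
#' @export
sequences_watched <- function(table) {
  dplyr::summarise(dplyr::group_by(table, .data$infant_id),
                   n_sequences = dplyr::n_distinct(.data$sequence),
                   .groups = "drop")
}

#' Exclude infants with too few trials
#'
#' Mirrors the study's inclusion rule: infants that carried out fewer than
#' `min_trials` trials in total are removed. The number excluded is kept in
#' the table's `n_excluded` attribute.
#'
#' @param table A `gaze_table`.
#' @param min_trials Minimum total trials to be retained (default 20;
#'   exactly 20 is retained).
#' @return The filtered `gaze_table`.
#' @export
apply_exclusion <- function(table, min_trials = 20L) {
  counts <- table(table$infant_id)
  keep_ids <- as.integer(names(counts)[counts >= min_trials])
  out <- table[table$infant_id %in% keep_ids, ]
  as_gaze_table(out,
                seed = attr(table, "seed"),
                config_hash = attr(table, "config_hash"),
                design_seed = attr(table, "design_seed"),
                n_excluded = length(counts) - length(keep_ids))
}

#' Write / read a gaze table as delimited text
#'
#' Columns `infant_id, sequence, trial, location, look_away,
#' saccadic_latency_ms, looking_time_ms`; missing values are empty fields;
#' indices are 1-based. Reading re-validates the truncation invariant (no
#' records after a look-away within an infant-sequence) and the missingness
#' pattern of the look-away trial.
#'
#' @param table A `gaze_table`.
#' @param path File path.
#' @return `write_gaze_table` returns `path` invisibly; `read_gaze_table`
#'   returns a `gaze_table`.
#' @export
write_gaze_table <- function(table, path) {
  cols <- c("infant_id", "sequence", "trial", "location", "look_away",
            "saccadic_latency_ms", "looking_time_ms")
  stopifnot(all(cols %in% names(table)))
  readr::write_csv(table[cols], path, na = "")
  invisible(path)
}

#' @rdname write_gaze_table
#' @export
read_gaze_table <- function(path) {
  cols <- c("infant_id", "sequence", "trial", "location", "look_away",
            "saccadic_latency_ms", "looking_time_ms")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          infant_id = readr::col_integer(),
                          sequence = readr::col_integer(),
                          trial = readr::col_integer(),
                          location = readr::col_integer(),
                          look_away = readr::col_integer(),
                          saccadic_latency_ms = readr::col_double(),
                          looking_time_ms = readr::col_double()))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("gaze table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) > 0) {
    df <- df[order(df$infant_id, df$sequence, df$trial), ]
    g <- paste(df$infant_id, df$sequence)
    csum <- stats::ave(df$look_away, g, FUN = cumsum)
    bad <- which((csum - df$look_away) > 0)
    if (length(bad) > 0) {
      stop("gaze table invalid at row ", bad[1],
           ": record after a look-away within infant ", df$infant_id[bad[1]],
           ", sequence ", df$sequence[bad[1]], call. = FALSE)
    }
    bad_na <- which(df$look_away == 1 &
                      (!is.na(df$saccadic_latency_ms) | !is.na(df$looking_time_ms)))
    if (length(bad_na) > 0) {
      stop("gaze table invalid at row ", bad_na[1],
           ": saccadic_latency_ms/looking_time_ms must be missing on a ",
           "look-away trial", call. = FALSE)
    }
  }
  as_gaze_table(tibble::as_tibble(df))
}
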