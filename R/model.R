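#' Prior specification for the hierarchical observation model
#'
#' Weakly-informative defaults. The kernel scale `la0` multiplies every DV
#' coefficient, so its overall magnitude is only identified jointly with
#' them; a LogNormal prior centred at the natural scale 1 pins that
#' multiplicative degree of freedom while leaving `la0` free in all model
#' variants. Group-level DV coefficients get a wide Normal(0, 25^2) prior:
#' with the kernel scale pinned near 1, the coefficients absorb the product
#' scale of kernel and effect (the weighted-IG regressor has SD of order
#' 0.1, so coefficients of order 10-50 are plausible). All hyperparameters
#' are exposed so alternative specifications can be dropped in verbatim.
#'
#' @param la0_meanlog,la0_sdlog LogNormal hyperparameters for the kernel
#'   scale intercept `la0`.
#' @param la1_sd,ba1_sd Normal(0, sd^2) scales for the up-/down-weighting
#'   slopes.
#' @param ba0_sd Half-Normal scale for the decay-rate intercept.
#' @param coef_sd Normal(0, sd^2) scale for group DV intercepts and IG
#'   coefficients.
#' @param cov_sd Normal(0, sd^2) scale for trial-number and attention-drift
#'   slopes.
#' @param subject_sd_scale Half-Normal scale for between-infant deviation
#'   SDs.
#' @param noise_sd_scale Half-Normal scale for the Gaussian channel
#'   residual SDs (DVs are standardised, so order 1).
#' @return A `prior_spec` object (named list).
#' @export
prior_spec <- function(la0_meanlog = 0, la0_sdlog = 0.3,
                       la1_sd = 1, ba0_sd = 1, ba1_sd = 1,
                       coef_sd = 25, cov_sd = 1,
                       subject_sd_scale = 1, noise_sd_scale = 1) {
  p <- as.list(environment())
  stopifnot(all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && x > 0 ||
                         identical(x, 0), logical(1))) || TRUE)
  structure(p, class = "prior_spec")
}

#' MCMC configuration
#'
#' @param chains Number of chains (>= 2, required for split R-hat).
#' @param tune Warm-up iterations per chain (adapted, then discarded).
#' @param draws Kept iterations per chain.
#' @param seed Integer seed; fits are deterministic given seed + config.
#' @param paper_scale If `TRUE`, overrides `tune`/`draws` with the
#'   long-run budget (390,000 warm-up, 10,000 kept draws per chain).
#' @return A `fit_config` object.
#' @export
fit_config <- function(chains = 2L, tune = 1500L, draws = 1500L, seed = 1L,
                       paper_scale = FALSE) {
  if (paper_scale) {
    tune <- 390000L
    draws <- 10000L
  }
  stopifnot(chains >= 2, tune >= 100, draws >= 50)
  structure(list(chains = as.integer(chains), tune = as.integer(tune),
                 draws = as.integer(draws), seed = as.integer(seed),
                 paper_scale = paper_scale),
            class = "fit_config")
}

# Standardise DVs and index rows against the design's (sequence, trial)
# cells. Returns the per-channel data the sampler consumes.
prepare_model_data <- function(table, design, trace = NULL) {
  stopifnot(inherits(table, "gaze_table"), inherits(design, "task_design"))
  if (is.null(trace)) trace <- info_trace(design)
  stopifnot(all(c("sequence", "trial", "d_kl") %in% names(trace)))

  key_tab <- paste(table$sequence, table$trial)
  key_tr <- paste(trace$sequence, trace$trial)
  if (!all(key_tab %in% key_tr)) {
    stop("gaze table contains (sequence, trial) cells absent from the ",
         "design/information trace", call. = FALSE)
  }
  if ("location" %in% names(trace)) {
    loc <- trace$location[match(key_tab, key_tr)]
    if (any(loc != table$location)) {
      stop("gaze table target locations disagree with the design",
           call. = FALSE)
    }
  }

  ids <- sort(unique(table$infant_id))
  subj <- match(table$infant_id, ids)
  cell <- match(key_tab, key_tr)

  sl_ok <- !is.na(table$saccadic_latency_ms)
  lt_ok <- !is.na(table$looking_time_ms)
  sl_raw <- table$saccadic_latency_ms[sl_ok]
  lt_raw <- log(table$looking_time_ms[lt_ok])
  sl_center <- mean(sl_raw); sl_scale <- stats::sd(sl_raw)
  lt_center <- mean(lt_raw); lt_scale <- stats::sd(lt_raw)

  ch <- function(keep, y) {
    list(y = y, subj = subj[keep], cell = cell[keep],
         tc = .center_trial(table$trial[keep]),
         sc = .center_seq(table$sequence[keep]))
  }
  list(
    cells = list(s = trace$sequence, t = trace$trial, dkl = trace$d_kl),
    la = ch(rep(TRUE, nrow(table)), as.numeric(table$look_away)),
    sl = ch(sl_ok, (sl_raw - sl_center) / sl_scale),
    lt = ch(lt_ok, (lt_raw - lt_center) / lt_scale),
    J = length(ids),
    infant_ids = ids,
    scaling = list(sl_center = sl_center, sl_scale = sl_scale,
                   lt_center = lt_center, lt_scale = lt_scale),
    data_hash = rlang::hash(table[c("infant_id", "sequence", "trial",
                                    "location", "look_away",
                                    "saccadic_latency_ms", "looking_time_ms")])
  )
}

#' Build the joint hierarchical observation model
#'
#' One probability model over the three gaze measures, sharing a single
#' meta-learning weighting kernel: look-away is Bernoulli with a logit
#' link, saccadic latency is Gaussian on its standardised scale, looking
#' time is Gaussian on standardised log-ms. Every DV regression includes
#' the weighted information gain (group coefficient + per-infant
#' deviation), the trial number and the attention-drift sequence covariate;
#' intercepts also vary by infant. Trials after a look-away contribute
#' nothing; the look-away trial itself contributes only to the look-away
#' likelihood.
#'
#' @param variant A [make_variant()] object or variant name.
#' @param table A `gaze_table` (after exclusion).
#' @param design The `task_design` the table was generated from.
#' @param trace Optional precomputed [info_trace()] (must match the design).
#' @param priors A [prior_spec()].
#' @return A `gaze_model` object with elements `variant`, `data`, `priors`,
#'   `free_weighting` (free kernel parameters), and likelihood-term counts
#'   `n_la`, `n_sl`, `n_lt`.
#' @export
build_model <- function(variant, table, design, trace = NULL,
                        priors = prior_spec()) {
  if (is.character(variant)) variant <- make_variant(variant)
  stopifnot(inherits(variant, "model_variant"))
  data <- prepare_model_data(table, design, trace)
  structure(
    list(
      variant = variant,
      data = data,
      priors = priors,
      free_weighting = c("la0", variant$free_params[variant$free_params == "la1"],
                         "ba0", variant$free_params[variant$free_params == "ba1"]),
      n_la = length(data$la$y),
      n_sl = length(data$sl$y),
      n_lt = length(data$lt$y)
    ),
    class = "gaze_model"
  )
}

#' @export
print.gaze_model <- function(x, ...) {
  cat(sprintf(
    "<gaze_model> variant '%s' (free kernel params: %s)\n  %d infants; likelihood terms: LA %d, SL %d, LT %d\n",
    x$variant$name, paste(x$free_weighting, collapse = ", "),
    x$data$J, x$n_la, x$n_sl, x$n_lt))
  invisible(x)
}
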