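#' Simulate weighted information gain for an unseen sequence
#'
#' Applies the posterior of the weighting kernel to a held-out sequence's
#' information-gain profile as if it had been encountered at different
#' positions in the session (e.g., as the 1st versus the 5th sequence).
#' With down-weighting and no up-weighting, the later-position curve is not
#' higher at the first trial but falls below the earlier-position curve on
#' later trials.
#'
#' @param fit A `gaze_fit` (typically of the full or downweight variant).
#' @param design The `task_design` containing the held-out sequence.
#' @param positions Sequence positions to compare (default `c(1, 5)`).
#' @param sequence Held-out sequence whose trial profile is used
#'   (default 16).
#' @param ndraws Posterior draws for the credible bands (default 500).
#' @param band_mass Credible-band probability mass (default 0.95).
#' @return A tibble with columns `position`, `trial`, `ig_mean` (curve at
#'   the posterior-mean kernel parameters), `band_lower`, `band_upper`.
#' @export
simulate_unseen_sequence <- function(fit, design, positions = c(1, 5),
                                     sequence = 16L, ndraws = 500L,
                                     band_mass = 0.95) {
  stopifnot(inherits(fit, "gaze_fit"), inherits(design, "task_design"))
  n_seq <- nrow(design$sequences)
  if (any(positions < 1 | positions > n_seq)) {
    stop("positions must lie in 1..", n_seq, call. = FALSE)
  }
  if (!(sequence %in% design$sequences$sequence)) {
    stop("held-out sequence ", sequence, " not in the design", call. = FALSE)
  }
  tr <- info_trace(design)
  prof <- tr[tr$sequence == sequence, ]
  dkl <- prof$d_kl[order(prof$trial)]
  trials <- sort(prof$trial)

  dm <- posterior_draws(fit, c("la0", "la1", "ba0", "ba1"))
  idx <- unique(round(seq(1, nrow(dm), length.out = min(ndraws, nrow(dm)))))
  dm <- dm[idx, , drop = FALSE]
  pm <- colMeans(dm)
  alpha <- (1 - band_mass) / 2

  rows <- lapply(positions, function(p) {
    mean_curve <- (pm[["la0"]] + pm[["la1"]] * p) *
      exp(-trials * (pm[["ba0"]] + pm[["ba1"]] * p)) * dkl
    draws_curve <- sapply(seq_along(trials), function(i) {
      (dm[, "la0"] + dm[, "la1"] * p) *
        exp(-trials[i] * (dm[, "ba0"] + dm[, "ba1"] * p)) * dkl[i]
    })
    draws_curve <- matrix(draws_curve, nrow = nrow(dm))
    tibble::tibble(
      position = p, trial = trials, ig_mean = mean_curve,
      band_lower = apply(draws_curve, 2, stats::quantile, probs = alpha),
      band_upper = apply(draws_curve, 2, stats::quantile, probs = 1 - alpha)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write the analysis report bundle
#'
#' Writes the available figures (posterior densities of the weighting
#' slopes, posterior-predictive overlays, the unseen-sequence simulation
#' panel, the efficiency-model marginal-effect panel), the model-comparison
#' table, and a JSON manifest of artifacts (seeds, config, hashes,
#' versions). Missing inputs are recorded as absent panels; the return
#' value distinguishes a partial bundle from a complete one.
#'
#' @param dir Output directory (created if needed).
#' @param fit A `gaze_fit` for the posterior-density panel, or `NULL`.
#' @param comparison A `comparison_table`, or `NULL`.
#' @param simulation Output of [simulate_unseen_sequence()], or `NULL`.
#' @param efficiency An `efficiency_fit`, or `NULL`.
#' @param ppc Output of [posterior_predictive()], or `NULL`.
#' @return List with `manifest_path`, `status` (`"complete"` or
#'   `"partial"`), `artifacts` and `absent`.
#' @export
make_report <- function(dir, fit = NULL, comparison = NULL, simulation = NULL,
                        efficiency = NULL, ppc = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      stop("cannot create report directory: ", dir, call. = FALSE)
    }
  }
  if (file.access(dir, 2) != 0) {
    stop("report directory is not writable: ", dir, call. = FALSE)
  }
  artifacts <- character(0)
  absent <- character(0)
  save_plot <- function(p, name) {
    path <- file.path(dir, name)
    grDevices::png(path, width = 1400, height = 900, res = 150)
    print(p)
    grDevices::dev.off()
    artifacts <<- c(artifacts, name)
  }

  if (!is.null(fit)) {
    params <- intersect(c("la1", "ba1", "mu_b_la", "mu_b_sl", "mu_b_lt"),
                        dimnames(fit$draws)[[3]])
    params <- setdiff(params, setdiff(c("la1", "ba1"),
                                      fit$model$variant$free_params))
    dd <- tidyr::pivot_longer(
      tibble::as_tibble(posterior_draws(fit, params)),
      dplyr::all_of(params), names_to = "parameter", values_to = "value")
    p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "posterior value", y = "density",
                    title = "Posterior distributions")
    save_plot(p, "posteriors.png")
    readr::write_csv(summarize_fit(fit), file.path(dir, "posterior_summary.csv"))
    artifacts <- c(artifacts, "posterior_summary.csv")
  } else {
    absent <- c(absent, "posteriors.png", "posterior_summary.csv")
  }

  if (!is.null(comparison)) {
    write_comparison(comparison, file.path(dir, "model_comparison.csv"))
    artifacts <- c(artifacts, "model_comparison.csv")
  } else {
    absent <- c(absent, "model_comparison.csv")
  }

  if (!is.null(simulation)) {
    p <- ggplot2::ggplot(simulation,
                         ggplot2::aes(x = .data$trial, y = .data$ig_mean,
                                      colour = factor(.data$position),
                                      fill = factor(.data$position))) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lower,
                                        ymax = .data$band_upper),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "trial", y = "weighted information gain (nats)",
                    colour = "sequence position", fill = "sequence position",
                    title = "Unseen-sequence information gain")
    save_plot(p, "unseen_sequence.png")
    readr::write_csv(simulation, file.path(dir, "unseen_sequence.csv"))
    artifacts <- c(artifacts, "unseen_sequence.csv")
  } else {
    absent <- c(absent, "unseen_sequence.png", "unseen_sequence.csv")
  }

  if (!is.null(efficiency)) {
    p <- ggplot2::ggplot(efficiency$marginal_effects,
                         ggplot2::aes(x = .data$trial, y = .data$mean)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hdi_lower,
                                        ymax = .data$hdi_upper),
                           alpha = 0.2) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = "trial", y = "effect of sequence number (sd units)",
                    title = "Marginal effect of sequence number on saccadic latency")
    save_plot(p, "efficiency_marginal_effects.png")
    readr::write_csv(efficiency$summaries, file.path(dir, "efficiency_summary.csv"))
    artifacts <- c(artifacts, "efficiency_summary.csv")
  } else {
    absent <- c(absent, "efficiency_marginal_effects.png", "efficiency_summary.csv")
  }

  if (!is.null(ppc) && nrow(ppc$sl_ms) > 0) {
    rep_df <- dplyr::bind_rows(lapply(seq_len(min(50, nrow(ppc$sl_ms))), function(i) {
      tibble::tibble(rep = i, sl = ppc$sl_ms[i, ])
    }))
    p <- ggplot2::ggplot() +
      ggplot2::geom_density(data = rep_df,
                            ggplot2::aes(x = .data$sl, group = .data$rep),
                            colour = "grey70", linewidth = 0.2) +
      ggplot2::geom_density(
        data = tibble::tibble(sl = ppc$observed_sl_ms),
        ggplot2::aes(x = .data$sl), colour = "black", linewidth = 0.8) +
      ggplot2::labs(x = "saccadic latency (ms)", y = "density",
                    title = "Posterior predictive check: saccadic latency")
    save_plot(p, "ppc_saccadic_latency.png")
  } else {
    absent <- c(absent, "ppc_saccadic_latency.png")
  }

  manifest <- list(
    package = "gazemeta",
    version = as.character(utils::packageVersion("gazemeta")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    fit_seed = if (!is.null(fit)) fit$config$seed else NULL,
    fit_variant = if (!is.null(fit)) fit$variant else NULL,
    data_hash = if (!is.null(fit)) fit$data_hash else NULL,
    artifacts = sort(artifacts),
    absent = sort(absent),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  list(manifest_path = manifest_path,
       status = if (length(absent) == 0) "complete" else "partial",
       artifacts = artifacts, absent = absent)
}
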