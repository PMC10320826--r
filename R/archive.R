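#' Persist / restore a fitted model as a plain-text posterior archive
#'
#' Writes the fit as a directory of delimited-text and JSON files grouped
#' the way standard inference-data containers are: `posterior.csv` (one row
#' per draw, with `chain` and `draw` index columns and one column per
#' parameter), `sample_stats.csv` (per-parameter split R-hat and effective
#' sample size), and `metadata.json` (variant, sampler configuration,
#' acceptance rates, data hash, convergence flag). The archive restores to
#' a summarisable fit: draws, diagnostics and metadata round-trip exactly
#' (text-representable values), while the model data themselves stay with
#' the gaze table and design they came from.
#'
#' @param fit A `gaze_fit`.
#' @param dir Archive directory (created if needed).
#' @return `write_fit_archive` returns `dir` invisibly; `read_fit_archive`
#'   returns a `gaze_fit_archive` object (draws array, diagnostics,
#'   metadata) that [summarize_fit()] and [posterior_draws()] accept.
#' @export
write_fit_archive <- function(fit, dir) {
  stopifnot(inherits(fit, "gaze_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pn <- dimnames(fit$draws)[[3]]
  n_draws <- dim(fit$draws)[1]
  n_chains <- dim(fit$draws)[2]
  flat <- do.call(rbind, lapply(seq_len(n_chains), function(ch) {
    m <- fit$draws[, ch, ]
    dim(m) <- c(n_draws, length(pn))
    m
  }))
  colnames(flat) <- pn
  post <- tibble::as_tibble(flat)
  post <- dplyr::bind_cols(
    tibble::tibble(chain = rep(seq_len(n_chains), each = n_draws),
                   draw = rep(seq_len(n_draws), n_chains)),
    post
  )
  readr::write_csv(post, file.path(dir, "posterior.csv"))
  readr::write_csv(fit$diagnostics, file.path(dir, "sample_stats.csv"))
  jsonlite::write_json(
    list(variant = fit$variant,
         chains = fit$config$chains, tune = fit$config$tune,
         draws = fit$config$draws, seed = fit$config$seed,
         accept = as.list(fit$accept),
         max_rhat = fit$max_rhat, converged = fit$converged,
         data_hash = fit$data_hash,
         free_weighting = fit$model$free_weighting),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fit_archive
#' @export
read_fit_archive <- function(dir) {
  post_path <- file.path(dir, "posterior.csv")
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(post_path) || !file.exists(meta_path)) {
    stop("not a fit archive (posterior.csv / metadata.json missing): ", dir,
         call. = FALSE)
  }
  post <- readr::read_csv(post_path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pn <- setdiff(names(post), c("chain", "draw"))
  chains <- sort(unique(post$chain))
  n_draws <- max(post$draw)
  arr <- array(NA_real_, c(n_draws, length(chains), length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (ch in chains) {
    block <- post[post$chain == ch, ]
    block <- block[order(block$draw), ]
    arr[, ch, ] <- as.matrix(block[pn])
  }
  diagnostics <- NULL
  stats_path <- file.path(dir, "sample_stats.csv")
  if (file.exists(stats_path)) {
    diagnostics <- readr::read_csv(stats_path, show_col_types = FALSE,
                                   progress = FALSE)
  }
  structure(
    list(draws = arr, diagnostics = diagnostics,
         max_rhat = meta$max_rhat, converged = meta$converged,
         variant = meta$variant, data_hash = meta$data_hash,
         config = list(chains = meta$chains, tune = meta$tune,
                       draws = meta$draws, seed = meta$seed),
         accept = unlist(meta$accept),
         model = list(variant = make_variant(meta$variant),
                      free_weighting = meta$free_weighting)),
    class = c("gaze_fit_archive", "gaze_fit")
  )
}
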