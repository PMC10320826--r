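#' Meta-learning weighting parameters
#'
#' The weighting kernel turns raw trialwise information gain `D_KL` into the
#' subjectively weighted information gain
#' `IG[s,t] = (la0 + la1*s) * exp(-t * (ba0 + ba1*s)) * D_KL[s,t]`,
#' with 1-based sequence index `s` and within-sequence trial index `t`.
#' `la0`/`la1` set the early up-weighting of information across sequences;
#' `ba0`/`ba1` set how quickly information is discounted over trials and how
#' that discounting steepens across sequences (late down-weighting). A
#' positive `ba1` means later sequences discount late trials more strongly.
#'
#' @param la0 Kernel scale intercept (> 0), default 1.
#' @param la1 Up-weighting slope over sequences, default 0.
#' @param ba0 Trialwise decay-rate intercept (>= 0), default 0.1.
#' @param ba1 Down-weighting slope of the decay rate over sequences,
#'   default 0.
#' @return A `weighting_params` object (named list).
#' @export
weighting_params <- function(la0 = 1, la1 = 0, ba0 = 0.1, ba1 = 0) {
  p <- list(la0 = la0, la1 = la1, ba0 = ba0, ba1 = ba1)
  stopifnot(all(vapply(p, is.numeric, logical(1))),
            all(lengths(p) == 1))
  if (la0 <= 0) stop("la0 must be > 0", call. = FALSE)
  if (ba0 < 0) stop("ba0 must be >= 0", call. = FALSE)
  structure(p, class = "weighting_params")
}

# Check the kernel stays valid (positive scale, non-negative decay rate)
# over the design's sequence range; returns the first offending s or 0L.
.weighting_violation <- function(params, s_range) {
  for (s in s_range) {
    if (params$la0 + params$la1 * s <= 0) return(c(s = s, which = 1L))
    if (params$ba0 + params$ba1 * s < 0) return(c(s = s, which = 2L))
  }
  NULL
}

#' Apply the meta-learning weighting kernel to an information-gain trace
#'
#' @param trace A tibble with columns `sequence`, `trial`, `d_kl`
#'   (see [info_trace()]).
#' @param params A [weighting_params()] object.
#' @return The trace with an added `ig_weighted` column.
#' @export
#' @examples
#' d <- generate_task_design(seed = 1)
#' tr <- info_trace(d)
#' w <- weight_info(tr, weighting_params(ba1 = 0.065))
weight_info <- function(trace, params) {
  stopifnot(inherits(params, "weighting_params"),
            all(c("sequence", "trial", "d_kl") %in% names(trace)))
  viol <- .weighting_violation(params, sort(unique(trace$sequence)))
  if (!is.null(viol)) {
    what <- if (viol[["which"]] == 1) "la0 + la1*s <= 0" else "ba0 + ba1*s < 0"
    stop("weighting parameters invalid at sequence ", viol[["s"]],
         ": ", what, call. = FALSE)
  }
  trace$ig_weighted <- weighting_kernel(trace$sequence, trace$trial, params) *
    trace$d_kl
  trace
}

#' Evaluate the weighting kernel itself
#'
#' @param s Sequence index (1-based), vectorised.
#' @param t Within-sequence trial index (1-based), vectorised.
#' @param params A [weighting_params()] object.
#' @return `(la0 + la1*s) * exp(-t * (ba0 + ba1*s))`.
#' @export
weighting_kernel <- function(s, t, params) {
  (params$la0 + params$la1 * s) * exp(-t * (params$ba0 + params$ba1 * s))
}

#' Define a model variant by clamping weighting slopes
#'
#' Four variants are compared: `"null"` (no change across sequences:
#' `la1 = ba1 = 0`), `"upweight"` (frees `la1` only), `"downweight"` (frees
#' `ba1` only) and `"full"` (frees both). The intercepts `la0` and `ba0`
#' are free in every variant.
#'
#' @param name One of `"null"`, `"upweight"`, `"downweight"`, `"full"`.
#' @param shared Optional [weighting_params()] supplying values for the
#'   clamped/forward evaluation; clamped slopes are forced to 0.
#' @return A `model_variant` object with fields `name`, `free_params`
#'   (character subset of `c("la1","ba1")`) and `params`.
#' @export
make_variant <- function(name, shared = weighting_params()) {
  free <- switch(name,
    "null" = character(0),
    "upweight" = "la1",
    "downweight" = "ba1",
    "full" = c("la1", "ba1"),
    stop("unknown model variant: ", name,
         " (expected null/upweight/downweight/full)", call. = FALSE)
  )
  params <- shared
  if (!("la1" %in% free)) params$la1 <- 0
  if (!("ba1" %in% free)) params$ba1 <- 0
  structure(list(name = name, free_params = free, params = params),
            class = "model_variant")
}

#' Write a weighted information-gain trace as delimited text
#'
#' Mirrors [write_info_trace()] with the extra `ig_weighted` column.
#'
#' @param trace A tibble from [weight_info()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_weighted_trace <- function(trace, path) {
  stopifnot(all(c("sequence", "trial", "d_kl", "ig_weighted") %in% names(trace)))
  readr::write_csv(trace, path)
  invisible(path)
}
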