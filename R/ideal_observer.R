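#' Create a fresh ideal-observer belief state
#'
#' The ideal observer tracks a Dirichlet-categorical belief over the K = 4
#' target locations. Beliefs start from the uniform prior pseudo-counts
#' `c(1, 1, 1, 1)` (every location equally likely, 25%) and are reset at the
#' start of every sequence: the observation counter `t` counts trials within
#' the current sequence only.
#'
#' @param prior_counts Dirichlet pseudo-counts, default `c(1, 1, 1, 1)`.
#' @return A `belief_state` object with fields `prior_counts`,
#'   `observed_counts` and `t`.
#' @export
#' @examples
#' st <- belief_state()
#' predictive(st)  # 0.25 everywhere
belief_state <- function(prior_counts = c(1, 1, 1, 1)) {
  stopifnot(is.numeric(prior_counts), all(prior_counts > 0))
  structure(
    list(
      prior_counts = as.numeric(prior_counts),
      observed_counts = integer(length(prior_counts)),
      t = 0L
    ),
    class = "belief_state"
  )
}

#' Update the belief state with an observed target location
#'
#' @param state A `belief_state`.
#' @param observed Integer location id in `1..K`.
#' @return The updated `belief_state` (t incremented, observed location's
#'   count incremented).
#' @export
update_belief <- function(state, observed) {
  stopifnot(inherits(state, "belief_state"))
  K <- length(state$prior_counts)
  if (!is.numeric(observed) || length(observed) != 1 ||
      is.na(observed) || observed != round(observed) ||
      observed < 1 || observed > K) {
    stop("observed location must be a single integer in 1..", K, call. = FALSE)
  }
  state$observed_counts[observed] <- state$observed_counts[observed] + 1L
  state$t <- state$t + 1L
  state
}

#' Posterior-predictive distribution over target locations
#'
#' `P(X)_i = (count_i + prior_i) / (t + sum(prior))`: the Dirichlet-smoothed
#' relative frequency of each location given everything observed so far in
#' the current sequence.
#'
#' @param state A `belief_state`.
#' @return Numeric vector of K strictly positive probabilities summing to 1.
#' @export
predictive <- function(state) {
  stopifnot(inherits(state, "belief_state"))
  num <- state$observed_counts + state$prior_counts
  num / sum(num)
}

#' Kullback-Leibler divergence between two predictive distributions
#'
#' `sum(p_new * log(p_new / p_old))` in nats; the information gained by the
#' observation that moved the belief from `p_old` to `p_new`.
#'
#' @param p_new,p_old Strictly positive probability vectors of equal length.
#' @return Non-negative scalar, in nats.
#' @export
kl_divergence <- function(p_new, p_old) {
  stopifnot(length(p_new) == length(p_old))
  if (any(p_new <= 0) || any(p_old <= 0)) {
    stop("KL divergence requires strictly positive probabilities", call. = FALSE)
  }
  sum(p_new * log(p_new / p_old))
}

#' Trialwise information-gain trace for a task design
#'
#' Runs the ideal observer over every sequence of the design (belief reset
#' at each sequence start) and records, per trial, the KL divergence between
#' the predictive distribution after and before the trial's observation.
#'
#' @param design A `task_design`.
#' @param prior_counts Dirichlet pseudo-counts, default uniform `c(1,1,1,1)`.
#' @return A tibble with columns `sequence`, `trial`, `location`, `d_kl`
#'   (nats), one row per trial, ordered by sequence then trial.
#' @export
info_trace <- function(design, prior_counts = c(1, 1, 1, 1)) {
  stopifnot(inherits(design, "task_design"))
  tr <- design$trials
  tr <- tr[order(tr$sequence, tr$trial), ]
  out <- numeric(nrow(tr))
  i <- 1L
  for (s in unique(tr$sequence)) {
    locs <- tr$location[tr$sequence == s]
    st <- belief_state(prior_counts)
    p_old <- predictive(st)
    for (x in locs) {
      st <- update_belief(st, x)
      p_new <- predictive(st)
      out[i] <- kl_divergence(p_new, p_old)
      p_old <- p_new
      i <- i + 1L
    }
  }
  tibble::tibble(
    sequence = tr$sequence,
    trial = tr$trial,
    location = tr$location,
    d_kl = out
  )
}

#' Write / read an information-gain trace as delimited text
#'
#' Columns `sequence`, `trial`, `d_kl` (plus `location` when present).
#'
#' @param trace A tibble as returned by [info_trace()].
#' @param path File path.
#' @return `write_info_trace` returns `path` invisibly; `read_info_trace`
#'   returns the tibble.
#' @export
write_info_trace <- function(trace, path) {
  stopifnot(all(c("sequence", "trial", "d_kl") %in% names(trace)))
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname write_info_trace
#' @export
read_info_trace <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("sequence", "trial", "d_kl"), names(tr))
  if (length(missing) > 0) {
    stop("info trace file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tr$sequence <- as.integer(tr$sequence)
  tr$trial <- as.integer(tr$trial)
  tr
}
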