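#' Generate the probabilistic cue-target task design
#'
#' Builds the 16-sequence schedule of target locations used by the visual
#' learning task: every sequence has 15 cue-target trials over K = 4 screen
#' quadrants, one high-likelihood location per sequence, and a predictability
#' level of 60%, 80% or 100% realised as an exact within-sequence count
#' (9, 12 or 15 of 15 trials at the high-likelihood location). Across the
#' whole design every location serves as target in exactly 25% of trials,
#' and every probabilistic sequence uses at least two distinct
#' low-probability locations. The first sequence is always fully
#' predictable; the remaining predictability levels are shuffled over
#' positions 2..16 by the seed.
#'
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param schedule List of `c(high_prob, count)` pairs; defaults to
#'   6 sequences at 0.60, 6 at 0.80 and 4 at 1.00.
#' @param n_trials Trials per sequence (default 15).
#' @param n_locations Number of target locations (default 4).
#'
#' @return A `task_design` object: a list with `sequences` (a tibble with one
#'   row per sequence: `sequence`, `high_prob`, `high_location`), `trials`
#'   (a tibble with one row per trial: `sequence`, `trial`, `location`,
#'   `high_prob`, `is_high_location`), `seed`, `n_trials`, `n_locations`.
#' @export
#' @examples
#' d <- generate_task_design(seed = 1)
#' table(d$trials$location)  # 60 each
generate_task_design <- function(seed,
                                 schedule = list(c(0.60, 6), c(0.80, 6), c(1.00, 4)),
                                 n_trials = 15L,
                                 n_locations = 4L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  n_trials <- as.integer(n_trials)
  n_locations <- as.integer(n_locations)

  probs <- vapply(schedule, `[`, numeric(1), 1)
  counts <- vapply(schedule, function(x) as.integer(x[2]), integer(1))
  if (any(counts < 0) || sum(counts) < 1) {
    stop("infeasible schedule: sequence counts must be positive", call. = FALSE)
  }
  high_counts <- probs * n_trials
  if (any(abs(high_counts - round(high_counts)) > 1e-9)) {
    stop("infeasible schedule: high_prob x n_trials must be an integer ",
         "(exact within-sequence counts)", call. = FALSE)
  }
  high_counts <- as.integer(round(high_counts))

  n_seq <- sum(counts)
  total_trials <- n_seq * n_trials
  if (total_trials %% n_locations != 0) {
    stop("infeasible schedule: total trial count ", total_trials,
         " does not divide evenly over ", n_locations,
         " locations (exact 25% marginal unsatisfiable)", call. = FALSE)
  }
  per_loc_target <- total_trials %/% n_locations

  levels_vec <- rep(probs, counts) # one level per sequence, unordered

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  # Order of predictability levels over sequence positions: the very first
  # sequence is always fully predictable; the rest are shuffled by seed.
  seq_levels <- .assign_levels(levels_vec)
  high_per_seq <- high_counts[match(seq_levels, probs)]
  off_per_seq <- n_trials - high_per_seq

  # Assign high-likelihood locations and off-trial locations so that the
  # exact per-location marginal and the >= 2 distinct low-probability
  # locations rule both hold. The assignment is a seeded randomized search:
  # the rare dead end restarts with fresh randomization.
  assignment <- NULL
  for (attempt in seq_len(100L)) {
    assignment <- .assign_locations(seq_levels, high_per_seq, off_per_seq,
                                    n_locations, per_loc_target)
    if (!is.null(assignment)) break
  }
  if (is.null(assignment)) {
    stop("infeasible schedule: cannot satisfy the exact per-location ",
         "marginal together with the multiple-low-location rule",
         call. = FALSE)
  }
  high_loc <- assignment$high_loc
  off_locs <- assignment$off_locs

  trials <- lapply(seq_len(n_seq), function(s) {
    locs <- c(rep(high_loc[s], high_per_seq[s]), off_locs[[s]])
    locs <- sample(locs) # within-sequence order shuffled by seed
    tibble::tibble(
      sequence = s,
      trial = seq_len(n_trials),
      location = as.integer(locs),
      high_prob = seq_levels[s],
      is_high_location = as.integer(locs) == high_loc[s]
    )
  })
  trials <- dplyr::bind_rows(trials)

  design <- structure(
    list(
      sequences = tibble::tibble(
        sequence = seq_len(n_seq),
        high_prob = seq_levels,
        high_location = high_loc
      ),
      trials = trials,
      seed = as.integer(seed),
      n_trials = n_trials,
      n_locations = n_locations
    ),
    class = "task_design"
  )
  violations <- validate_design(design)
  if (length(violations) > 0) {
    stop("generated design failed validation: ",
         paste(violations, collapse = "; "), call. = FALSE)
  }
  design
}

# One randomized attempt at assigning high-likelihood and off-trial
# locations under the exact marginal; returns NULL on a dead end.
.assign_locations <- function(seq_levels, high_per_seq, off_per_seq,
                              n_locations, per_loc_target) {
  n_seq <- length(seq_levels)
  # High locations: round-robin over a seeded permutation within each
  # predictability level, so high-trial totals stay near-balanced.
  loc_perm <- sample.int(n_locations)
  high_loc <- integer(n_seq)
  for (p in unique(seq_levels)) {
    idx <- which(seq_levels == p)
    high_loc[idx] <- loc_perm[((seq_along(idx) - 1) %% n_locations) + 1]
    loc_perm <- sample.int(n_locations)
  }
  deficit <- per_loc_target -
    tabulate(rep(high_loc, high_per_seq), nbins = n_locations)
  if (any(deficit < 0) || sum(deficit) != sum(off_per_seq)) return(NULL)

  # Off trials: repeatedly place one trial of the location with the largest
  # remaining deficit into the eligible sequence with the most remaining
  # off slots. The per-sequence cap (off - 1 per location) guarantees every
  # probabilistic sequence ends up with >= 2 distinct off locations.
  taken <- matrix(0L, n_seq, n_locations)
  rem <- off_per_seq
  cap <- pmax(off_per_seq - 1L, 0L)
  while (sum(deficit) > 0) {
    cand <- which(deficit == max(deficit))
    L <- if (length(cand) > 1) sample(cand, 1) else cand
    ok <- which(rem > 0 & high_loc != L & taken[, L] < cap)
    if (length(ok) == 0) return(NULL)
    best <- ok[rem[ok] == max(rem[ok])]
    s <- if (length(best) > 1) sample(best, 1) else best
    taken[s, L] <- taken[s, L] + 1L
    rem[s] <- rem[s] - 1L
    deficit[L] <- deficit[L] - 1L
  }
  if (any(rem != 0)) return(NULL)
  off_locs <- lapply(seq_len(n_seq), function(s) {
    rep(seq_len(n_locations), taken[s, ])
  })
  list(high_loc = high_loc, off_locs = off_locs)
}

# First position fully predictable when a 100% level exists, rest shuffled.
.assign_levels <- function(levels_vec) {
  if (any(levels_vec == 1)) {
    rest <- levels_vec[-match(1, levels_vec)]
    c(1, sample(rest))
  } else {
    sample(levels_vec)
  }
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(value) {
  if (is.null(value)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", value, envir = globalenv())
  }
}

#' Validate a task design against its structural invariants
#'
#' Checks sequence length, the exact high-location trial counts implied by
#' each sequence's predictability level, the exact equal per-location
#' marginal across the whole design, and the requirement that probabilistic
#' sequences spread their off-trials over at least two distinct locations.
#'
#' @param design A `task_design` object.
#' @return Character vector of human-readable violations; empty if the
#'   design is valid. Validation never raises.
#' @export
validate_design <- function(design) {
  out <- character(0)
  if (!inherits(design, "task_design")) {
    return("not a task_design object")
  }
  tr <- design$trials
  sq <- design$sequences
  K <- design$n_locations
  nt <- design$n_trials

  for (s in sq$sequence) {
    rows <- tr[tr$sequence == s, ]
    if (nrow(rows) != nt) {
      out <- c(out, sprintf("sequence %d: expected %d trials, found %d",
                            s, nt, nrow(rows)))
      next
    }
    hp <- sq$high_prob[sq$sequence == s]
    hl <- sq$high_location[sq$sequence == s]
    expected_high <- as.integer(round(hp * nt))
    n_high <- sum(rows$location == hl)
    if (n_high != expected_high) {
      out <- c(out, sprintf(
        "sequence %d: %d trials at high-likelihood location, expected %d (level %.0f%%)",
        s, n_high, expected_high, 100 * hp))
    }
    if (hp < 1) {
      off <- rows$location[rows$location != hl]
      if (length(unique(off)) < 2) {
        out <- c(out, sprintf(
          "sequence %d: probabilistic sequence must use >= 2 distinct low-probability locations",
          s))
      }
    }
    if (any(rows$location < 1 | rows$location > K)) {
      out <- c(out, sprintf("sequence %d: location outside 1..%d", s, K))
    }
  }

  marg <- tabulate(tr$location, nbins = K)
  if (length(unique(marg)) != 1) {
    out <- c(out, sprintf(
      "per-location marginal not equal: counts %s over locations 1..%d",
      paste(marg, collapse = "/"), K))
  }
  out
}

#' Write / read a task design as a delimited text table
#'
#' Columns: `sequence`, `trial`, `location`, `high_prob`,
#' `is_high_location` (0/1), with 1-based sequence and trial indices.
#'
#' @param design A `task_design` object.
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   `task_design` object.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  tr <- design$trials
  tr$is_high_location <- as.integer(tr$is_high_location)
  readr::write_csv(tr, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sequence", "trial", "location", "high_prob", "is_high_location")
  missing <- setdiff(required, names(tr))
  if (length(missing) > 0) {
    stop("design file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tr$sequence <- as.integer(tr$sequence)
  tr$trial <- as.integer(tr$trial)
  tr$location <- as.integer(tr$location)
  tr$is_high_location <- as.logical(tr$is_high_location)
  sq <- dplyr::summarise(
    dplyr::group_by(tr, .data$sequence),
    high_prob = .data$high_prob[1],
    high_location = {
      counts <- table(.data$location)
      as.integer(names(counts)[which.max(counts)])
    },
    .groups = "drop"
  )
  # With recorded flags, prefer them for the high location.
  flagged <- dplyr::summarise(
    dplyr::group_by(tr[tr$is_high_location, ], .data$sequence),
    hl = .data$location[1], .groups = "drop"
  )
  sq$high_location[match(flagged$sequence, sq$sequence)] <- flagged$hl
  structure(
    list(
      sequences = tibble::tibble(
        sequence = sq$sequence,
        high_prob = sq$high_prob,
        high_location = sq$high_location
      ),
      trials = tr[order(tr$sequence, tr$trial), ],
      seed = NA_integer_,
      n_trials = max(tr$trial),
      n_locations = max(4L, max(tr$location))
    ),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  lv <- table(x$sequences$high_prob)
  cat(sprintf(
    "<task_design> %d sequences x %d trials, %d locations; levels: %s\n",
    nrow(x$sequences), x$n_trials, x$n_locations,
    paste(sprintf("%s%% x%d", 100 * as.numeric(names(lv)), lv), collapse = ", ")))
  invisible(x)
}
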