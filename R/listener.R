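#' Distance-based simulated listener
#'
#' A softmax observer over category barycenters: the probability of choosing
#' category c for a stimulus at position x in the component space is
#' proportional to `exp(-sensitivity * duration_gain(d) * ||x - b_c||)`.
#' It is the simplest observer consistent with a general categorization
#' process that reads the distribution of spectral-envelope features; it
#' exists to exercise the pipeline, not to model human listeners.
#'
#' `sensitivity = 0` yields uniform guessing; large sensitivity approaches a
#' nearest-barycenter classifier. `duration_gain` (non-decreasing in duration
#' by default) encodes that longer gates give a cleaner percept.
#'
#' @param sensitivity Non-negative inverse temperature (per unit distance in
#'   component-score units).
#' @param duration_gain Named numeric vector mapping duration (ms, as names)
#'   to a positive multiplier on sensitivity.
#' @param seed Integer seed for response draws.
#' @return A `listener_model` object.
#' @export
listener_model <- function(sensitivity = 0.6,
                           duration_gain = c(
                             "20" = 0.25, "30" = 0.45, "50" = 0.8,
                             "100" = 1.4, "200" = 2.4
                           ),
                           seed = 1L) {
  if (sensitivity < 0) stop_parameter("`sensitivity` must be >= 0.")
  if (any(duration_gain <= 0)) stop_parameter("All duration gains must be > 0.")
  structure(
    list(
      sensitivity = sensitivity,
      duration_gain = duration_gain,
      seed = as.integer(seed)
    ),
    class = "listener_model"
  )
}

#' Build a blocked trial list
#'
#' Trials are blocked by increasing gate duration — all 20 ms stimuli first
#' (in seeded random order), then all 30 ms stimuli, and so on — matching a
#' gating procedure in which duration increases over the session.
#'
#' @param stimuli Stimulus tibble (needs `stimulus_id`, `duration_ms`).
#' @param seed Integer seed for the within-block shuffles.
#' @return `stimuli` reordered, with a `trial_id` column prepended.
#' @export
make_trial_list <- function(stimuli, seed = 1L) {
  durations <- sort(unique(stimuli$duration_ms))
  idx <- integer(0)
  for (bi in seq_along(durations)) {
    block <- which(stimuli$duration_ms == durations[bi])
    perm <- with_seed(derive_seed(seed, bi), sample.int(length(block)))
    idx <- c(idx, block[perm])
  }
  out <- stimuli[idx, ]
  dplyr::bind_cols(tibble(trial_id = seq_len(nrow(out))), out)
}

softmax_choice_probs <- function(x, barycenters, beta) {
  d <- vapply(rownames(barycenters), function(lab) {
    sqrt(sum((x - barycenters[lab, ])^2))
  }, numeric(1))
  u <- -beta * (d - min(d))
  p <- exp(u)
  p / sum(p)
}

# Barycenter matrix (labels x components) from summarize_categories() output.
barycenter_matrix <- function(summaries, n_components = NULL) {
  if (is.null(n_components)) n_components <- max(summaries$component)
  labs <- unique(summaries$label)
  m <- matrix(
    NA_real_, nrow = length(labs), ncol = n_components,
    dimnames = list(labs, NULL)
  )
  for (lab in labs) {
    s <- summaries[summaries$label == lab & summaries$component <= n_components, ]
    m[lab, s$component] <- s$barycenter
  }
  if (anyNA(m)) stop_parameter("Barycenters missing for some label/component.")
  m
}

#' Simulate one participant's forced-choice responses
#'
#' @param model A [listener_model()].
#' @param trial_list Blocked trials from [make_trial_list()].
#' @param scores Score matrix with stimulus-id rownames (from a fitted
#'   `feature_space`); only the barycenter's components are used.
#' @param summaries Category summary tibble from [summarize_categories()]
#'   covering all three categories.
#' @param participant_id Identifier recorded on each trial.
#' @return A tibble of trials: participant_id, trial_id, stimulus_id,
#'   true_label, duration_ms, normalization, response_label.
#' @export
simulate_listener <- function(model, trial_list, scores, summaries,
                              participant_id = "P01") {
  if (!inherits(model, "listener_model")) stop_parameter("`model` must be a listener_model.")
  bary <- barycenter_matrix(summaries)
  if (!all(category_labels() %in% rownames(bary))) {
    stop_parameter("Barycenters must cover all three categories.")
  }
  missing <- setdiff(trial_list$stimulus_id, rownames(scores))
  if (length(missing) > 0L) {
    stop_data(sprintf("No scores for stimuli: %s",
                      paste(utils::head(missing, 5), collapse = ", ")))
  }
  k <- ncol(bary)
  labs <- rownames(bary)
  responses <- with_seed(derive_seed(model$seed, sum(utf8ToInt(participant_id))), {
    vapply(seq_len(nrow(trial_list)), function(i) {
      x <- scores[trial_list$stimulus_id[i], seq_len(k)]
      g <- model$duration_gain[as.character(trial_list$duration_ms[i])]
      if (is.na(g)) g <- 1
      p <- softmax_choice_probs(x, bary, model$sensitivity * g)
      labs[findInterval(runif(1), cumsum(p)) + 1L]
    }, character(1))
  })
  tibble(
    participant_id = participant_id,
    trial_id = trial_list$trial_id,
    stimulus_id = trial_list$stimulus_id,
    true_label = trial_list$label,
    duration_ms = trial_list$duration_ms,
    normalization = trial_list$normalization,
    response_label = responses
  )
}

#' Simulate a panel of participants
#'
#' @inheritParams simulate_listener
#' @param stimuli Stimulus tibble; each participant receives a fresh blocked
#'   trial list built from it.
#' @param n_participants Number of simulated listeners; each gets its own
#'   trial order and response stream derived from the model seed.
#' @param id_prefix Prefix for participant identifiers.
#' @return Row-bound trial tibble over all participants.
#' @export
simulate_participants <- function(model, stimuli, scores, summaries,
                                  n_participants = 18, id_prefix = "P") {
  purrr::map_dfr(seq_len(n_participants), function(i) {
    trials <- make_trial_list(stimuli, seed = derive_seed(model$seed, 7000, i))
    pid <- sprintf("%s%02d", id_prefix, i)
    m <- model
    m$seed <- derive_seed(model$seed, 8000, i)
    simulate_listener(m, trials, scores, summaries, participant_id = pid)
  })
}

#' Maximum-likelihood recovery of listener sensitivity
#'
#' Profiles the log-likelihood of a response log under the softmax observer
#' over a grid of sensitivity values (duration gains held at the generating
#' model's values), then refines around the grid maximum.
#'
#' @param trials Response log from [simulate_listener()].
#' @param scores,summaries As in [simulate_listener()].
#' @param duration_gain Gain mapping assumed known.
#' @param grid Sensitivity values to profile.
#' @return List with `sensitivity` (the MLE) and `loglik` (grid tibble).
#' @export
estimate_sensitivity <- function(trials, scores, summaries,
                                 duration_gain = NULL,
                                 grid = seq(0.02, 4, by = 0.02)) {
  bary <- barycenter_matrix(summaries)
  k <- ncol(bary)
  labs <- rownames(bary)
  x <- scores[trials$stimulus_id, seq_len(k), drop = FALSE]
  dmat <- vapply(labs, function(lab) {
    sqrt(rowSums((x - matrix(bary[lab, ], nrow(x), k, byrow = TRUE))^2))
  }, numeric(nrow(x)))
  g <- if (is.null(duration_gain)) rep(1, nrow(trials)) else {
    gg <- duration_gain[as.character(trials$duration_ms)]
    gg[is.na(gg)] <- 1
    gg
  }
  chosen <- match(trials$response_label, labs)
  nll <- function(s) {
    u <- -s * g * dmat
    u <- u - apply(u, 1, max)
    -sum(u[cbind(seq_len(nrow(u)), chosen)] - log(rowSums(exp(u))))
  }
  vals <- vapply(grid, nll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(nll, c(lo, hi))
  list(
    sensitivity = opt$minimum,
    loglik = tibble(sensitivity = grid, nll = vals)
  )
}
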