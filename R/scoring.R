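#' Confusion matrix of a response log
#'
#' @param trials Trial tibble with `true_label` and `response_label`.
#' @return A `confusion_matrix` object: list with `counts` (3x3 integer
#'   matrix, rows = true label, columns = response) and `percent` (each row
#'   divided by its row sum, x100).
#' @export
confusion_matrix <- function(trials) {
  if (nrow(trials) == 0L) stop_parameter("`trials` is empty.")
  labs <- category_labels()
  counts <- table(
    factor(trials$true_label, levels = labs),
    factor(trials$response_label, levels = labs)
  )
  counts <- matrix(as.integer(counts), 3, 3, dimnames = dimnames(counts))
  percent <- sweep(counts, 1, pmax(rowSums(counts), 1), `/`) * 100
  structure(list(counts = counts, percent = percent), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Response percentages by true category (rows):\n")
  print(round(x$percent))
  invisible(x)
}

#' Accuracy index for one category
#'
#' The hit/false-alarm index `Hit/N - FA/(2N)`, where N is the number of
#' items of the category (so 2N items belong to the other two categories).
#' Chance level is 0 (equal hit and false-alarm rates); the index ranges from
#' -0.5 (all false alarms, no hits) to 1 (perfect).
#'
#' @param trials Trial tibble; the design must be balanced (equal trial
#'   counts per true label).
#' @param label Category to score.
#' @return A tibble row: label, hits, false_alarms, n, index.
#' @export
accuracy_index <- function(trials, label) {
  assert_label(label)
  counts <- table(trials$true_label)
  if (length(unique(as.integer(counts))) != 1L) {
    stop_parameter(sprintf(
      "Accuracy index requires a balanced design; per-label counts: %s",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = ", ")
    ))
  }
  n <- as.integer(counts[[1]])
  hits <- sum(trials$true_label == label & trials$response_label == label)
  fa <- sum(trials$true_label != label & trials$response_label == label)
  tibble(
    label = label, hits = hits, false_alarms = fa, n = n,
    index = hits / n - fa / (2 * n)
  )
}

#' Expected accuracy index of a uniform random responder
#'
#' Closed form for a responder choosing uniformly among `n_labels` labels in
#' a balanced design: `E[Hit/N] = 1/K` and, with `(K-1)N` other-category
#' items, `E[FA/(2N)] = (K-1)/(2K)`. For the three-category design the two
#' terms coincide and the chance level is exactly 0.
#'
#' @param n_labels Number of response categories (default 3).
#' @return The expected index.
#' @export
chance_accuracy_index <- function(n_labels = 3) {
  1 / n_labels - (n_labels - 1) / (2 * n_labels)
}

#' False-alarm rate for one category
#'
#' Fraction of the trials whose true label is NOT `label` that were
#' nonetheless answered with `label` (denominator 2N in a balanced
#' three-category design, consistent with the accuracy index).
#'
#' @inheritParams accuracy_index
#' @return A fraction in `[0, 1]`.
#' @export
false_alarm_rate <- function(trials, label) {
  assert_label(label)
  other <- trials$true_label != label
  sum(other & trials$response_label == label) / sum(other)
}

#' Accuracy index per participant, duration and category
#'
#' @param trials Trial tibble over one or more participants.
#' @return Tibble: participant_id, duration_ms, label, hits, false_alarms,
#'   n, index — one accuracy record per cell.
#' @export
accuracy_by_duration <- function(trials) {
  cells <- dplyr::distinct(trials, .data$participant_id, .data$duration_ms)
  purrr::pmap_dfr(cells, function(participant_id, duration_ms) {
    sub <- trials[trials$participant_id == participant_id &
                    trials$duration_ms == duration_ms, ]
    purrr::map_dfr(category_labels(), function(lab) {
      dplyr::bind_cols(
        tibble(participant_id = participant_id, duration_ms = duration_ms),
        accuracy_index(sub, lab)
      )
    })
  })
}

#' One-sample test of accuracy indices against chance
#'
#' Two-sided one-sample t test of per-participant accuracy indices against
#' the chance level 0. With zero variance across participants the test is
#' degenerate and is reported as such rather than computed.
#'
#' @param indices Numeric vector of per-participant accuracy indices (>= 2).
#' @return Tibble row: n, mean_index, t, df, p_value, degenerate.
#' @export
above_chance_test <- function(indices) {
  if (length(indices) < 2L) stop_parameter("Need indices from >= 2 participants.")
  if (sd(indices) == 0) {
    return(tibble(
      n = length(indices), mean_index = mean(indices),
      t = NA_real_, df = length(indices) - 1L, p_value = NA_real_,
      degenerate = TRUE
    ))
  }
  tt <- t.test(indices, mu = 0)
  tibble(
    n = length(indices), mean_index = mean(indices),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, degenerate = FALSE
  )
}

#' Read / write response logs
#'
#' Delimited-text response logs with header columns participant_id,
#' trial_id, stimulus_id, true_label, duration_ms, normalization,
#' response_label.
#'
#' @param trials Trial tibble.
#' @param path CSV file path.
#' @return `write_response_log()` returns `path` invisibly;
#'   `read_response_log()` returns the trial tibble.
#' @export
write_response_log <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_log
#' @export
read_response_log <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
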