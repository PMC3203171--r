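#' Assemble the per-stimulus regression dataset
#'
#' Joins per-stimulus accuracy (proportion of trials answered correctly,
#' pooled over participants) with the acoustic predictors: within- and
#' between-category distance in the component space, gate duration, and the
#' mean RMS power of the presented waveform (a loudness proxy, used as a
#' predictor in the peak-normalized condition where levels vary).
#'
#' @param trials Trial tibble covering every stimulus at least once.
#' @param features Distance tibble from [distance_features()].
#' @param stimuli Stimulus tibble (for duration and RMS power).
#' @return A tibble with one row per stimulus: stimulus_id, label, accuracy,
#'   within_distance, between_distance, duration_ms, mean_rms, n_trials.
#' @export
build_dataset <- function(trials, features, stimuli) {
  acc <- trials |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(
      accuracy = mean(.data$response_label == .data$true_label),
      n_trials = dplyr::n(), .groups = "drop"
    )
  missing_feat <- setdiff(stimuli$stimulus_id, features$stimulus_id)
  if (length(missing_feat) > 0L) {
    stop_data(sprintf("Stimuli without distance features: %s",
                      paste(utils::head(missing_feat, 5), collapse = ", ")))
  }
  missing_trial <- setdiff(stimuli$stimulus_id, acc$stimulus_id)
  if (length(missing_trial) > 0L) {
    stop_data(sprintf("Stimuli without any trial: %s",
                      paste(utils::head(missing_trial, 5), collapse = ", ")))
  }
  stimuli |>
    dplyr::transmute(
      stimulus_id = .data$stimulus_id, label = .data$label,
      duration_ms = .data$duration_ms, mean_rms = .data$rms
    ) |>
    dplyr::inner_join(
      dplyr::select(features, "stimulus_id", "within_distance", "between_distance"),
      by = "stimulus_id"
    ) |>
    dplyr::inner_join(acc, by = "stimulus_id") |>
    dplyr::select(
      "stimulus_id", "label", "accuracy", "within_distance",
      "between_distance", "duration_ms", "mean_rms", "n_trials"
    )
}

#' Standardized multiple regression of accuracy on acoustic predictors
#'
#' Ordinary least squares on z-scored response and predictors (sample SD,
#' n-1), so the slopes are standardized coefficients (betas). Reports the
#' coefficient table (beta, SE, t, p) and the model summary: R-squared,
#' adjusted R-squared `1 - (1 - R2)(n - 1)/(n - p - 1)`, the overall F with
#' its degrees of freedom, and the residual sum of squares (SSE) of the
#' standardized fit.
#'
#' @param dataset Tibble from [build_dataset()] (or any tibble containing
#'   `response` and `predictors` columns).
#' @param response Response column name (default `"accuracy"`).
#' @param predictors Character vector of predictor column names; default is
#'   the full peak-condition set (drop `"mean_rms"` for the RMS condition,
#'   where levels are equalized).
#' @param condition_threshold Condition-number threshold above which the
#'   predictor set is declared collinear.
#' @return A `regression_result`: list with `coefficients` tibble, `r2`,
#'   `adjusted_r2`, `f`, `df1`, `df2`, `f_p_value`, `sse`, `n`, `p`.
#' @export
fit_standardized <- function(dataset,
                             response = "accuracy",
                             predictors = c(
                               "within_distance", "between_distance",
                               "duration_ms", "mean_rms"
                             ),
                             condition_threshold = 1e8) {
  cols <- c(response, predictors)
  if (!all(cols %in% names(dataset))) {
    stop_parameter(sprintf("Missing columns: %s",
                           paste(setdiff(cols, names(dataset)), collapse = ", ")))
  }
  df <- dataset[cols]
  if (!all(complete.cases(df))) stop_data("Dataset contains missing values.")
  n <- nrow(df)
  p <- length(predictors)
  if (n < p + 2L) stop_parameter("Need at least p + 2 rows.")
  z <- as.data.frame(lapply(df, function(x) {
    s <- sd(x)
    if (s == 0) stop_degenerate("A regression column is constant; cannot z-score.")
    (x - mean(x)) / s
  }))
  kappa_x <- kappa(as.matrix(z[predictors]), exact = TRUE)
  if (kappa_x > condition_threshold) {
    stop_degenerate(sprintf(
      "Predictors are collinear (condition number %.3g): %s",
      kappa_x, paste(predictors, collapse = ", ")
    ))
  }
  fml <- stats::as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = z)
  sm <- summary(fit)
  ct <- sm$coefficients[predictors, , drop = FALSE]
  structure(
    list(
      coefficients = tibble(
        predictor = predictors,
        beta = unname(ct[, 1]), se = unname(ct[, 2]),
        t = unname(ct[, 3]), p_value = unname(ct[, 4])
      ),
      r2 = sm$r.squared,
      adjusted_r2 = sm$adj.r.squared,
      f = unname(sm$fstatistic[1]),
      df1 = unname(sm$fstatistic[2]),
      df2 = unname(sm$fstatistic[3]),
      f_p_value = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                            sm$fstatistic[3], lower.tail = FALSE)),
      sse = sum(fit$residuals^2),
      n = n, p = p
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "Standardized OLS: R2 = %.3f, adj R2 = %.3f, F(%d, %d) = %.2f, SSE = %.2f, n = %d\n",
    x$r2, x$adjusted_r2, x$df1, x$df2, x$f, x$sse, x$n
  ))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}
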