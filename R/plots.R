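#' Barycenter-and-ellipse map of the component space
#'
#' Scatter of stimulus scores on the first two components with, per
#' category, the barycenter and an ellipse whose half-axes are the
#' per-component dispersions (population SD) — the standard display of
#' category spread in the PCA plane. Optionally faceted by duration.
#'
#' @param space A fitted `feature_space`.
#' @param labels Category label per fitted stimulus.
#' @param durations_ms Optional duration per stimulus; when given the map is
#'   faceted by duration.
#' @return A ggplot object.
#' @export
plot_category_map <- function(space, labels, durations_ms = NULL) {
  df <- tibble(
    pc1 = space$scores[, 1], pc2 = space$scores[, 2], label = labels
  )
  if (!is.null(durations_ms)) df$duration_ms <- durations_ms
  ell <- function(sub) {
    s <- summarize_categories(
      structure(
        list(scores = cbind(sub$pc1, sub$pc2), fitted_on = NULL),
        class = "feature_space"
      ),
      sub$label, n_components = 2
    )
    th <- seq(0, 2 * pi, length.out = 120)
    purrr::map_dfr(unique(s$label), function(lab) {
      b <- s[s$label == lab, ]
      tibble(
        label = lab,
        pc1 = b$barycenter[1] + b$dispersion[1] * cos(th),
        pc2 = b$barycenter[2] + b$dispersion[2] * sin(th)
      )
    })
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                        colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8)
  if (is.null(durations_ms)) {
    p <- p + ggplot2::geom_path(data = ell(df), linewidth = 0.8)
  } else {
    eld <- df |>
      dplyr::group_by(.data$duration_ms) |>
      dplyr::group_modify(~ ell(.x)) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_path(data = eld, linewidth = 0.8) +
      ggplot2::facet_wrap(~duration_ms)
  }
  p + ggplot2::labs(x = "PC1", y = "PC2", colour = "category") +
    ggplot2::theme_minimal()
}

#' Mean excitation patterns per category
#'
#' Average pattern (with a 95% confidence band across stimuli) per category,
#' on a log-frequency axis.
#'
#' @param features Feature table from [feature_table()].
#' @return A ggplot object.
#' @export
plot_excitation_profiles <- function(features) {
  long <- features |>
    tidyr::pivot_longer(
      -c("stimulus_id", "label", "duration_ms", "normalization"),
      names_to = "cf", values_to = "rms"
    ) |>
    dplyr::mutate(cf = as.numeric(.data$cf)) |>
    dplyr::group_by(.data$label, .data$normalization, .data$cf) |>
    dplyr::summarise(
      mean = mean(.data$rms),
      lo = mean(.data$rms) - 1.96 * sd(.data$rms) / sqrt(dplyr::n()),
      hi = mean(.data$rms) + 1.96 * sd(.data$rms) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cf, y = .data$mean,
                                     colour = .data$label, fill = .data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~normalization, scales = "free_y") +
    ggplot2::labs(x = "channel center frequency (Hz)", y = "mean channel RMS",
                  colour = "category", fill = "category") +
    ggplot2::theme_minimal()
}

#' Accuracy as a function of gate duration
#'
#' @param accuracy Tibble from `run_all()`'s `accuracy` element
#'   (normalization, duration_ms, label, mean_index).
#' @return A ggplot object.
#' @export
plot_accuracy <- function(accuracy) {
  ggplot2::ggplot(accuracy, ggplot2::aes(x = .data$duration_ms,
                                         y = .data$mean_index,
                                         colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~normalization) +
    ggplot2::labs(x = "gate duration (ms)", y = "mean accuracy index",
                  colour = "category") +
    ggplot2::theme_minimal()
}
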