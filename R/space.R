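#' Global PCA of excitation patterns
#'
#' Fits a principal component analysis over all stimuli (the "global" space:
#' all durations and both normalization conditions together). In
#' `CORRELATION` mode (default) channels are centered and scaled by their
#' sample SD before the eigendecomposition — the mode whose variable
#' projections form the classic correlation circle; `COVARIANCE` mode only
#' centers. Component signs follow the convention that the largest-magnitude
#' loading entry of each component is positive.
#'
#' @param patterns Matrix (stimuli x channels), e.g. from
#'   [excitation_patterns()]; rownames are stimulus ids.
#' @param mode `"CORRELATION"` or `"COVARIANCE"`.
#' @return A `feature_space` object: list with `loadings` (channels x
#'   components, orthonormal columns), `scores` (stimuli x components),
#'   `variance_fractions` (non-increasing, summing to 1 over all components),
#'   `sdev`, `center`, `scale`, `mode`, `fitted_on` (stimulus ids),
#'   `center_frequencies` (if present on `patterns`).
#' @export
fit_pca <- function(patterns, mode = c("CORRELATION", "COVARIANCE")) {
  mode <- match.arg(mode)
  if (!is.matrix(patterns) || nrow(patterns) < 2L) {
    stop_parameter("`patterns` must be a matrix with at least 2 rows.")
  }
  if (mode == "CORRELATION") {
    sds <- apply(patterns, 2, sd)
    if (any(sds == 0)) {
      bad <- colnames(patterns)[sds == 0]
      if (is.null(bad)) bad <- which(sds == 0)
      stop_degenerate(sprintf(
        "Constant channel(s) cannot be scaled in CORRELATION mode: %s",
        paste(bad, collapse = ", ")
      ))
    }
  }
  fit <- prcomp(patterns, center = TRUE, scale. = (mode == "CORRELATION"))
  loadings <- fit$rotation
  scores <- fit$x
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- fit$sdev^2
  structure(
    list(
      loadings = loadings,
      scores = scores,
      variance_fractions = ev / sum(ev),
      sdev = fit$sdev,
      center = fit$center,
      scale = if (mode == "CORRELATION") fit$scale else rep(1, ncol(patterns)),
      mode = mode,
      fitted_on = rownames(patterns),
      center_frequencies = attr(patterns, "center_frequencies")
    ),
    class = "feature_space"
  )
}

#' @export
print.feature_space <- function(x, ...) {
  vf <- round(100 * x$variance_fractions[seq_len(min(5, length(x$variance_fractions)))])
  cat(sprintf(
    "<feature_space> %d stimuli x %d channels, %s mode\n  variance: %s%%\n",
    nrow(x$scores), nrow(x$loadings), x$mode, paste(vf, collapse = "/")
  ))
  invisible(x)
}

#' Correlation circle of the original channels
#'
#' Pearson correlation of each original variable (frequency channel) with the
#' first two component score columns — the projection of the 80 frequency
#' bands onto the component plane. The channels most correlated with each
#' component identify the frequency bands that drive it.
#'
#' @param space A fitted `feature_space`.
#' @return A tibble (channel, center_frequency_hz, cor_pc1, cor_pc2) with
#'   attribute `top_channels`: the argmax-|correlation| channel index per
#'   component.
#' @export
correlation_circle <- function(space) {
  if (!inherits(space, "feature_space")) stop_parameter("`space` must be a feature_space.")
  s1 <- space$scores[, 1]
  s2 <- space$scores[, 2]
  if (sd(s1) == 0 || sd(s2) == 0) {
    stop_degenerate("A score column has zero variance; cannot correlate.")
  }
  # centered/scaled channel values reconstructed from the full score matrix
  chan <- space$scores %*% t(space$loadings)
  c1 <- as.numeric(cor(chan, s1))
  c2 <- as.numeric(cor(chan, s2))
  cfs <- space$center_frequencies
  out <- tibble(
    channel = seq_len(ncol(chan)),
    center_frequency_hz = if (is.null(cfs)) NA_real_ else cfs,
    cor_pc1 = c1,
    cor_pc2 = c2
  )
  attr(out, "top_channels") <- c(pc1 = which.max(abs(c1)), pc2 = which.max(abs(c2)))
  out
}

#' Per-category barycenters and dispersions in the component space
#'
#' The barycenter is the mean score of a category's items; the dispersion is
#' the population SD (divide by n) of the scores per component — the ellipse
#' half-axes used to display category spread on the first two components.
#'
#' @param space A fitted `feature_space`.
#' @param labels Category label per fitted stimulus (recycled against
#'   `space$fitted_on` order).
#' @param n_components Number of leading components to summarize (default 2).
#' @return A tibble: label, component, barycenter, dispersion, n_items.
#' @export
summarize_categories <- function(space, labels, n_components = 2) {
  if (n_components > ncol(space$scores)) {
    stop_parameter("`n_components` exceeds the number of fitted components.")
  }
  if (length(labels) != nrow(space$scores)) {
    stop_parameter("`labels` must have one entry per fitted stimulus.")
  }
  if (!all(labels %in% category_labels())) {
    stop_data(sprintf(
      "Unknown label(s): %s",
      paste(setdiff(unique(labels), category_labels()), collapse = ", ")
    ))
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  rows <- list()
  for (lab in unique(labels)) {
    sc <- space$scores[labels == lab, seq_len(n_components), drop = FALSE]
    rows[[lab]] <- tibble(
      label = lab,
      component = seq_len(n_components),
      barycenter = colMeans(sc),
      dispersion = apply(sc, 2, pop_sd),
      n_items = nrow(sc)
    )
  }
  dplyr::bind_rows(rows)
}

#' Within- and between-category Euclidean distances
#'
#' For each stimulus, in the space of the first `n_components` score
#' dimensions: the within-category distance is the average Euclidean distance
#' to the other members of its own category; the between-category distance is
#' the average distance to all members of the other categories. These are the
#' acoustic predictors of categorization accuracy.
#'
#' @param space A fitted `feature_space`.
#' @param labels Category label per fitted stimulus.
#' @param n_components Number of leading score dimensions (default 2).
#' @return A tibble: stimulus_id, label, within_distance, between_distance.
#' @export
distance_features <- function(space, labels, n_components = 2) {
  if (length(labels) != nrow(space$scores)) {
    stop_parameter("`labels` must have one entry per fitted stimulus.")
  }
  counts <- table(labels)
  if (any(counts < 2)) {
    stop_parameter(sprintf(
      "Every category needs >= 2 items; singleton(s): %s",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  sc <- space$scores[, seq_len(n_components), drop = FALSE]
  d <- as.matrix(dist(sc))
  same <- outer(labels, labels, `==`)
  diag(same) <- NA  # exclude self from the within average
  within <- rowMeans(ifelse(same, d, NA), na.rm = TRUE)
  between <- rowMeans(ifelse(!same & !is.na(same), d, NA), na.rm = TRUE)
  tibble(
    stimulus_id = if (is.null(space$fitted_on)) as.character(seq_along(labels)) else space$fitted_on,
    label = labels,
    within_distance = as.numeric(within),
    between_distance = as.numeric(between)
  )
}
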