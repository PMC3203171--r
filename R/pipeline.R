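#' Full-pipeline configuration
#'
#' A single nested-list configuration drives the end-to-end analysis. Two
#' profiles are shipped: `"paper"` — the study-scale conditions (44.1 kHz,
#' 30 s sources, 10 sources per category) — and `"desk"` — a reduced-scale
#' variant (22.05 kHz, 10 s sources, 8 sources per category) with the same
#' category structure and the same factorial design, sized for quick runs.
#' Both use 20 excerpts per (category, duration) cell over the durations
#' 20, 30, 50, 100 and 200 ms, i.e. 300 stimuli per normalization condition.
#'
#' @param seed Master integer seed; every stage derives its own sub-seed.
#' @param profile `"desk"` or `"paper"`.
#' @param corpus_type `"default"` (shipped category structure) or
#'   `"scenario"` (the rms-boosts-voice-separation positive control).
#' @return A `pipeline_config` nested list.
#' @export
default_config <- function(seed = 1L, profile = c("desk", "paper"),
                           corpus_type = c("default", "scenario")) {
  profile <- match.arg(profile)
  corpus_type <- match.arg(corpus_type)
  scale <- switch(profile,
    paper = list(sample_rate = 44100L, duration_s = 30, n_sources = 10L, f_high = 15000),
    desk = list(sample_rate = 22050L, duration_s = 10, n_sources = 8L, f_high = 10000)
  )
  config <- list(
    seed = as.integer(seed),
    profile = profile,
    corpus = list(
      type = corpus_type,
      n_sources = scale$n_sources,
      duration_s = scale$duration_s,
      sample_rate = scale$sample_rate
    ),
    design = list(
      excerpts_per_cell = 20L,
      durations_ms = c(20, 30, 50, 100, 200),
      silence_threshold_db = -40,
      peak_target = 0.99,
      # the scenario compares distances across conditions, so it equalizes
      # at the excerpts' natural mean level rather than a fixed low target
      rms_target = if (corpus_type == "scenario") "auto" else 0.05,
      max_redraws = 1000L
    ),
    filterbank = list(
      n_channels = 80L,
      f_low = 50,
      f_high = scale$f_high,
      output_scale = "LINEAR_RMS"
    ),
    pca = list(mode = "CORRELATION", n_components = 2L),
    listener = list(
      sensitivity = 0.6,
      duration_gain = list(`20` = 0.25, `30` = 0.45, `50` = 0.8,
                           `100` = 1.4, `200` = 2.4),
      n_participants = list(PEAK = 18L, RMS = 19L)
    )
  )
  validate_config(config)
}

#' Validate (and normalize) a pipeline configuration
#'
#' Checks every field before any computation; returns the normalized config.
#'
#' @param config A nested configuration list.
#' @return The validated `pipeline_config`.
#' @export
validate_config <- function(config) {
  need <- c("seed", "corpus", "design", "filterbank", "pca", "listener")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0L) {
    stop_parameter(sprintf("Config is missing: %s", paste(missing, collapse = ", ")))
  }
  if (!config$corpus$type %in% c("default", "scenario")) {
    stop_parameter("`corpus$type` must be 'default' or 'scenario'.")
  }
  if (!config$pca$mode %in% c("CORRELATION", "COVARIANCE")) {
    stop_parameter("`pca$mode` must be 'CORRELATION' or 'COVARIANCE'.")
  }
  if (config$pca$n_components < 1) stop_parameter("`pca$n_components` must be >= 1.")
  config$seed <- as.integer(config$seed)
  config$corpus$n_sources <- as.integer(config$corpus$n_sources)
  config$corpus$sample_rate <- as.integer(config$corpus$sample_rate)
  config$design$excerpts_per_cell <- as.integer(config$design$excerpts_per_cell)
  config$design$durations_ms <- as.numeric(config$design$durations_ms)
  config$design$max_redraws <- as.integer(config$design$max_redraws)
  config$filterbank$n_channels <- as.integer(config$filterbank$n_channels)
  config$pca$n_components <- as.integer(config$pca$n_components)
  config$listener$duration_gain <-
    lapply(config$listener$duration_gain, as.numeric)
  config$listener$n_participants <-
    lapply(config$listener$n_participants, as.integer)
  # build one filterbank config now so range errors surface during validation
  filterbank_config(
    n_channels = config$filterbank$n_channels,
    f_low = config$filterbank$f_low, f_high = config$filterbank$f_high,
    sample_rate = config$corpus$sample_rate,
    output_scale = config$filterbank$output_scale
  )
  structure(config, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   validated config. The pair round-trips losslessly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

config_synth_specs <- function(config) {
  maker <- switch(config$corpus$type,
    default = default_synth_specs,
    scenario = scenario_synth_specs
  )
  maker(
    seed = derive_seed(config$seed, 1),
    n_sources = config$corpus$n_sources,
    duration_s = config$corpus$duration_s,
    sample_rate = config$corpus$sample_rate
  )
}

config_filterbank <- function(config) {
  filterbank_config(
    n_channels = config$filterbank$n_channels,
    f_low = config$filterbank$f_low,
    f_high = config$filterbank$f_high,
    sample_rate = config$corpus$sample_rate,
    output_scale = config$filterbank$output_scale
  )
}

config_listener <- function(config) {
  listener_model(
    sensitivity = config$listener$sensitivity,
    duration_gain = unlist(config$listener$duration_gain),
    seed = derive_seed(config$seed, 3)
  )
}

#' Derive the RMS-normalization condition from extracted peak excerpts
#'
#' The two normalization conditions share the same excerpts: sources are
#' peak-normalized and segmented once, and the RMS condition applies an
#' additional RMS equalization to each cut excerpt. Stimulus ids keep their
#' ordinal part with the condition suffix switched from `_P` to `_R`.
#'
#' @param stimuli Peak-condition stimulus tibble from [extract_gates()].
#' @param target_rms Target RMS level, or `"auto"` to equalize at the mean
#'   RMS of the peak-condition excerpts (level-matched equalization).
#' @return The RMS-condition stimulus tibble.
#' @export
as_rms_condition <- function(stimuli, target_rms = 0.05) {
  if (identical(target_rms, "auto")) target_rms <- mean(stimuli$rms)
  clipped <- 0L
  stimuli$samples <- lapply(stimuli$samples, function(x) {
    withCallingHandlers(
      rms_normalize(x, target_rms = target_rms),
      soundgate_clip_warning = function(w) {
        clipped <<- clipped + 1L
        invokeRestart("muffleWarning")
      }
    )
  })
  stimuli$normalization <- "RMS"
  stimuli$stimulus_id <- sub("_P$", "_R", stimuli$stimulus_id)
  stimuli$rms <- vapply(stimuli$samples, rms_level, numeric(1))
  stimuli$peak <- vapply(stimuli$samples, function(x) max(abs(x)), numeric(1))
  attr(stimuli, "n_clipped") <- clipped
  stimuli
}

#' Restrict a fitted space to a subset of stimuli
#'
#' Keeps the global basis (loadings, center, scale, variance fractions) and
#' subsets the score rows — used for per-condition and per-duration
#' summaries and distances inside the global component space.
#'
#' @param space A `feature_space`.
#' @param ids Stimulus ids to keep (must all be fitted).
#' @return A `feature_space` whose `scores`/`fitted_on` cover only `ids`.
#' @export
subset_space <- function(space, ids) {
  i <- match(ids, space$fitted_on)
  if (anyNA(i)) stop_data("Some ids were not fitted in this space.")
  space$scores <- space$scores[i, , drop = FALSE]
  space$fitted_on <- space$fitted_on[i]
  space
}

# FNV-1a over the YAML serialization: cheap stable config fingerprint.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(yaml::as.yaml(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), as.integer(b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes every stage for both normalization conditions: corpus synthesis,
#' peak normalization, gated-excerpt extraction (shared cuts; the RMS
#' condition additionally RMS-equalizes each excerpt), excitation patterns,
#' the global PCA with correlation circle and category summaries (pooled and
#' per duration), simulated listeners, confusion/accuracy scoring with
#' above-chance tests, and the standardized regressions linking distances to
#' accuracy. Deterministic given the config (master seed included).
#'
#' @param config A `pipeline_config` from [default_config()] or
#'   [read_config()].
#' @param out_dir Optional output directory; when given, every table is
#'   written as CSV plus a `run_manifest.yaml` with the config, its hash and
#'   stage counts.
#' @param keep_audio Keep waveforms in the returned stimulus tibbles
#'   (default FALSE to keep the result light).
#' @return Invisibly, a list: config, sources_manifest, stimuli (manifest
#'   rows for both conditions), features, space, variance_fractions,
#'   correlation_circle, category_summaries, distance_features, trials,
#'   confusions, accuracy, accuracy_cells, above_chance, regressions, log.
#' @export
run_all <- function(config, out_dir = NULL, keep_audio = FALSE) {
  config <- validate_config(config)
  log <- list()

  specs <- config_synth_specs(config)
  sources <- generate_corpus(specs)
  sources <- lapply(sources, peak_normalize, target_peak = config$design$peak_target)
  log$n_sources <- length(sources)

  design <- design_spec(
    excerpts_per_cell = config$design$excerpts_per_cell,
    durations_ms = config$design$durations_ms,
    normalization = "PEAK",
    silence_threshold_db = config$design$silence_threshold_db,
    rms_target = config$design$rms_target,
    max_redraws = config$design$max_redraws,
    seed = derive_seed(config$seed, 2)
  )
  stim_peak <- extract_gates(sources, design)
  stim_rms <- as_rms_condition(stim_peak, target_rms = config$design$rms_target)
  log$n_stimuli_per_condition <- nrow(stim_peak)
  log$n_rms_clipped <- attr(stim_rms, "n_clipped")

  fb <- config_filterbank(config)
  stimuli <- dplyr::bind_rows(stim_peak, stim_rms)
  patterns <- excitation_patterns(stimuli, fb)
  features <- feature_table(stimuli, patterns)

  space <- fit_pca(patterns, mode = config$pca$mode)
  circle <- correlation_circle(space)
  nc <- config$pca$n_components

  summaries <- list()
  distances <- list()
  for (cond in c("PEAK", "RMS")) {
    ids <- stimuli$stimulus_id[stimuli$normalization == cond]
    labs <- stimuli$label[stimuli$normalization == cond]
    durs <- stimuli$duration_ms[stimuli$normalization == cond]
    sub <- subset_space(space, ids)
    summaries[[cond]] <- dplyr::bind_cols(
      tibble(normalization = cond, duration_ms = NA_real_),
      summarize_categories(sub, labs, n_components = nc)
    )
    for (d in sort(unique(durs))) {
      sub_d <- subset_space(space, ids[durs == d])
      summaries[[paste(cond, d)]] <- dplyr::bind_cols(
        tibble(normalization = cond, duration_ms = d),
        summarize_categories(sub_d, labs[durs == d], n_components = nc)
      )
    }
    distances[[cond]] <- dplyr::bind_cols(
      tibble(normalization = cond),
      distance_features(sub, labs, n_components = nc)
    )
  }
  summaries <- dplyr::bind_rows(summaries)
  distances <- dplyr::bind_rows(distances)

  model <- config_listener(config)
  trials <- list()
  for (cond in c("PEAK", "RMS")) {
    stim_cond <- stimuli[stimuli$normalization == cond, ]
    summ_cond <- summaries[summaries$normalization == cond &
                             is.na(summaries$duration_ms), ]
    m <- model
    m$seed <- derive_seed(model$seed, match(cond, c("PEAK", "RMS")))
    trials[[cond]] <- simulate_participants(
      m, stim_cond, space$scores, summ_cond,
      n_participants = config$listener$n_participants[[cond]],
      id_prefix = substr(cond, 1, 1)
    )
  }
  trials <- dplyr::bind_rows(trials)

  confusions <- lapply(c(PEAK = "PEAK", RMS = "RMS"), function(cond) {
    confusion_matrix(trials[trials$normalization == cond, ])
  })
  acc_cells <- trials |>
    dplyr::group_by(.data$normalization) |>
    dplyr::group_modify(~ accuracy_by_duration(.x)) |>
    dplyr::ungroup()
  accuracy <- acc_cells |>
    dplyr::group_by(.data$normalization, .data$duration_ms, .data$label) |>
    dplyr::summarise(mean_index = mean(.data$index), .groups = "drop")
  above <- acc_cells |>
    dplyr::group_by(.data$normalization, .data$duration_ms, .data$label) |>
    dplyr::group_modify(~ above_chance_test(.x$index)) |>
    dplyr::ungroup()

  regressions <- list()
  for (cond in c("PEAK", "RMS")) {
    stim_cond <- stimuli[stimuli$normalization == cond, ]
    ds <- build_dataset(
      trials[trials$normalization == cond, ],
      distances[distances$normalization == cond, ],
      stim_cond
    )
    preds <- c("within_distance", "between_distance", "duration_ms")
    if (cond == "PEAK") preds <- c(preds, "mean_rms")
    regressions[[cond]] <- fit_standardized(ds, predictors = preds)
  }

  result <- list(
    config = config,
    sources_manifest = tibble(
      source_id = vapply(sources, `[[`, character(1), "source_id"),
      label = vapply(sources, `[[`, character(1), "label"),
      n_samples = vapply(sources, function(s) length(s$samples), numeric(1)),
      sample_rate = config$corpus$sample_rate
    ),
    stimuli = if (keep_audio) stimuli else stimulus_manifest(stimuli),
    features = features,
    space = space,
    variance_fractions = space$variance_fractions,
    correlation_circle = circle,
    category_summaries = summaries,
    distance_features = distances,
    trials = trials,
    confusions = confusions,
    accuracy = accuracy,
    accuracy_cells = acc_cells,
    above_chance = above,
    regressions = regressions,
    log = log
  )

  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  invisible(result)
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) write.csv(x, file.path(out_dir, name), row.names = FALSE)
  w(result$sources_manifest, "sources_manifest.csv")
  w(result$stimuli[setdiff(names(result$stimuli), "samples")], "stimulus_manifest.csv")
  w(result$features, "feature_table.csv")
  scores <- as.data.frame(result$space$scores[, 1:5, drop = FALSE])
  names(scores) <- paste0("PC", seq_len(ncol(scores)))
  w(cbind(stimulus_id = result$space$fitted_on, scores), "pca_scores.csv")
  w(
    data.frame(
      component = seq_along(result$variance_fractions),
      variance_fraction = result$variance_fractions
    ),
    "pca_variance.csv"
  )
  w(result$correlation_circle, "correlation_circle.csv")
  w(result$category_summaries, "category_summaries.csv")
  w(result$distance_features, "distance_features.csv")
  w(result$trials, "trials.csv")
  for (cond in names(result$confusions)) {
    pc <- round(result$confusions[[cond]]$percent)
    w(
      cbind(stimulus = rownames(pc), as.data.frame(pc)),
      sprintf("confusion_%s.csv", tolower(cond))
    )
  }
  w(result$accuracy, "accuracy_by_duration.csv")
  w(result$above_chance, "above_chance.csv")
  for (cond in names(result$regressions)) {
    r <- result$regressions[[cond]]
    w(r$coefficients, sprintf("regression_coefficients_%s.csv", tolower(cond)))
    w(
      data.frame(
        r2 = r$r2, adjusted_r2 = r$adjusted_r2, f = r$f, df1 = r$df1,
        df2 = r$df2, sse = r$sse, n = r$n, p = r$p
      ),
      sprintf("regression_summary_%s.csv", tolower(cond))
    )
  }
  yaml::write_yaml(
    list(
      config_hash = config_hash(result$config),
      seed = result$config$seed,
      log = result$log,
      config = unclass(result$config)
    ),
    file.path(out_dir, "run_manifest.yaml")
  )
  invisible(out_dir)
}
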