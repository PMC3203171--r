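#' Factorial design for gated-excerpt extraction
#'
#' The default reproduces the 20 excerpts x 3 categories x 5 durations
#' (20, 30, 50, 100, 200 ms) design, i.e. 300 stimuli per normalization
#' condition.
#'
#' @param excerpts_per_cell Excerpts per (category, duration) cell (>= 1).
#' @param durations_ms Set of gate durations in milliseconds.
#' @param categories Category labels in the design.
#' @param normalization `"PEAK"` (excerpts presented as cut from the
#'   peak-normalized sources) or `"RMS"` (each excerpt additionally
#'   RMS-equalized after segmentation).
#' @param silence_threshold_db Quasi-silence rejection threshold in dBFS; an
#'   excerpt with RMS level strictly below it is rejected and redrawn.
#' @param rms_target Target RMS level for the RMS condition (full scale = 1),
#'   or `"auto"` to equalize at the mean RMS of the cut excerpts
#'   (level-matched equalization, used when distances are compared across
#'   normalization conditions).
#' @param max_redraws Cap on consecutive silent redraws per excerpt.
#' @param seed Integer seed for onset sampling.
#' @return A `design_spec` object.
#' @export
design_spec <- function(excerpts_per_cell = 20,
                        durations_ms = c(20, 30, 50, 100, 200),
                        categories = category_labels(),
                        normalization = c("PEAK", "RMS"),
                        silence_threshold_db = -40,
                        rms_target = 0.05,
                        max_redraws = 1000,
                        seed = 1L) {
  normalization <- match.arg(normalization)
  if (excerpts_per_cell < 1) stop_parameter("`excerpts_per_cell` must be >= 1.")
  if (any(durations_ms <= 0)) stop_parameter("All durations must be > 0 ms.")
  if (anyDuplicated(durations_ms)) stop_parameter("Durations must be distinct.")
  lapply(categories, assert_label)
  if (anyDuplicated(categories)) stop_parameter("Categories must be distinct.")
  if (!(identical(rms_target, "auto") ||
        (is.numeric(rms_target) && length(rms_target) == 1L && rms_target > 0))) {
    stop_parameter("`rms_target` must be a positive level or \"auto\".")
  }
  structure(
    list(
      excerpts_per_cell = as.integer(excerpts_per_cell),
      durations_ms = sort(as.numeric(durations_ms)),
      categories = as.character(categories),
      normalization = normalization,
      silence_threshold_db = silence_threshold_db,
      rms_target = rms_target,
      max_redraws = as.integer(max_redraws),
      seed = as.integer(seed)
    ),
    class = "design_spec"
  )
}

#' Peak-normalize a clip
#'
#' Rescales so the maximum absolute sample equals `target_peak`; the waveform
#' shape is unchanged (output is a positive scalar multiple of the input).
#' Applied to whole source recordings before segmentation.
#'
#' @param clip An `audio_clip` or numeric sample vector.
#' @param target_peak Target peak amplitude in `(0, 1]`.
#' @return Same type as `clip`, rescaled.
#' @export
peak_normalize <- function(clip, target_peak = 0.99) {
  if (target_peak <= 0 || target_peak > 1) {
    stop_parameter("`target_peak` must be in (0, 1].")
  }
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  peak <- max(abs(x))
  if (peak == 0) stop_degenerate("Cannot peak-normalize an all-zero signal.")
  y <- x * (target_peak / peak)
  if (inherits(clip, "audio_clip")) {
    clip$samples <- y
    clip
  } else {
    y
  }
}

#' RMS-normalize a signal
#'
#' Rescales so the root-mean-square level equals `target_rms`. In the
#' pipeline this is applied to excerpts AFTER segmentation (sources are
#' peak-normalized, then cut, then optionally RMS-equalized). If the rescaled
#' signal would exceed full scale it is hard-limited at +/-1 and a warning of
#' class `soundgate_clip_warning` is raised.
#'
#' @param clip An `audio_clip` or numeric sample vector.
#' @param target_rms Target RMS level (> 0, full scale = 1).
#' @return Same type as `clip`, rescaled.
#' @export
rms_normalize <- function(clip, target_rms = 0.05) {
  if (target_rms <= 0) stop_parameter("`target_rms` must be > 0.")
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  r <- sqrt(mean(x^2))
  if (r == 0) stop_degenerate("Cannot RMS-normalize a zero-RMS signal.")
  y <- x * (target_rms / r)
  if (max(abs(y)) > 1) {
    warn(
      sprintf(
        "RMS normalization to %.3g pushed the signal beyond full scale; hard-limited at +/-1.",
        target_rms
      ),
      class = "soundgate_clip_warning"
    )
    y <- pmax(pmin(y, 1), -1)
  }
  if (inherits(clip, "audio_clip")) {
    clip$samples <- y
    clip
  } else {
    y
  }
}

#' Is an excerpt silent or quasi-silent?
#'
#' TRUE iff `20*log10(RMS(excerpt))` is strictly below `threshold_db`
#' (an all-zero excerpt is always quasi-silent). Excerpts flagged by this
#' predicate are removed from the stimulus set and redrawn.
#'
#' @param excerpt Numeric sample vector.
#' @param threshold_db Threshold in dBFS.
#' @return Logical scalar.
#' @export
is_quasi_silent <- function(excerpt, threshold_db = -40) {
  dbfs_level(excerpt) < threshold_db
}

#' Cut randomly placed gated excerpts from source recordings
#'
#' For every (category, duration) cell, draws `excerpts_per_cell` excerpts:
#' a source of that category is picked uniformly, then a 0-based onset
#' uniformly over valid positions; quasi-silent excerpts are rejected and
#' redrawn (bounded by `max_redraws`). Sources must already be
#' peak-normalized. If the design's normalization is `"RMS"`, every excerpt
#' is RMS-equalized after cutting.
#'
#' @param sources List of `audio_clip`s, all at the same sample rate, each
#'   longer than the longest gate duration.
#' @param design A [design_spec()].
#' @return A tibble of stimuli with one row per excerpt: `stimulus_id`,
#'   `label`, `duration_ms`, `normalization`, `source_id`, `onset_sample`
#'   (0-based, half-open interval), `rms`, `peak`, `sample_rate`, and a
#'   `samples` list-column holding the waveform.
#' @export
extract_gates <- function(sources, design) {
  if (!inherits(design, "design_spec")) stop_parameter("`design` must be a design_spec.")
  if (length(sources) == 0L) stop_parameter("`sources` must be non-empty.")
  fs <- sources[[1]]$sample_rate
  if (!all(vapply(sources, function(s) s$sample_rate, numeric(1)) == fs)) {
    stop_parameter("All sources must share one sample rate.")
  }
  src_labels <- vapply(sources, function(s) s$label, character(1))
  max_len <- max(round(design$durations_ms * fs / 1000))
  too_short <- vapply(sources, function(s) length(s$samples) <= max_len, logical(1))
  if (any(too_short)) {
    stop_parameter(sprintf(
      "Sources shorter than the longest gate (%d samples): %s",
      max_len,
      paste(vapply(sources[too_short], function(s) s$source_id, character(1)), collapse = ", ")
    ))
  }

  rows <- list()
  for (ci in seq_along(design$categories)) {
    cat_label <- design$categories[ci]
    cand <- which(src_labels == cat_label)
    if (length(cand) == 0L) {
      stop_parameter(sprintf("No sources with label %s.", cat_label))
    }
    for (di in seq_along(design$durations_ms)) {
      dur_ms <- design$durations_ms[di]
      len <- max(1L, as.integer(round(dur_ms * fs / 1000)))
      cell_seed <- derive_seed(design$seed, ci, di)
      cell <- with_seed(cell_seed, {
        out <- vector("list", design$excerpts_per_cell)
        for (k in seq_len(design$excerpts_per_cell)) {
          draws <- 0L
          repeat {
            draws <- draws + 1L
            if (draws > design$max_redraws) {
              abort(
                sprintf(
                  "Could not draw a non-silent %g ms excerpt for category %s after %d redraws.",
                  dur_ms, cat_label, design$max_redraws
                ),
                class = "soundgate_infeasible_design_error"
              )
            }
            src <- sources[[cand[floor(runif(1) * length(cand)) + 1L]]]
            n_onsets <- length(src$samples) - len + 1L
            onset <- floor(runif(1) * n_onsets)   # 0-based
            seg <- src$samples[(onset + 1L):(onset + len)]
            if (!is_quasi_silent(seg, design$silence_threshold_db)) break
          }
          out[[k]] <- list(
            label = cat_label, duration_ms = dur_ms, source_id = src$source_id,
            onset_sample = onset, samples = seg
          )
        }
        out
      })
      rows <- c(rows, cell)
    }
  }

  stim <- tibble(
    stimulus_id = sprintf("S%03d_%s", seq_along(rows),
                          substr(design$normalization, 1, 1)),
    label = vapply(rows, `[[`, character(1), "label"),
    duration_ms = vapply(rows, `[[`, numeric(1), "duration_ms"),
    normalization = design$normalization,
    source_id = vapply(rows, `[[`, character(1), "source_id"),
    onset_sample = vapply(rows, `[[`, numeric(1), "onset_sample"),
    sample_rate = fs,
    samples = lapply(rows, `[[`, "samples")
  )
  if (design$normalization == "RMS") {
    target <- if (identical(design$rms_target, "auto")) {
      mean(vapply(stim$samples, rms_level, numeric(1)))
    } else {
      design$rms_target
    }
    stim$samples <- lapply(stim$samples, rms_normalize, target_rms = target)
  }
  stim$rms <- vapply(stim$samples, rms_level, numeric(1))
  stim$peak <- vapply(stim$samples, function(x) max(abs(x)), numeric(1))
  stim
}

#' Stimulus manifest without waveforms
#'
#' @param stimuli Tibble from [extract_gates()].
#' @return The manifest columns only (no `samples` list-column), suitable for
#'   writing as CSV.
#' @export
stimulus_manifest <- function(stimuli) {
  dplyr::select(stimuli, -"samples")
}
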