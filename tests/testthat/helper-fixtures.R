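# Shared fixtures, built in code. Heavy objects (full desk-profile pipeline
# runs) are computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Full pipeline run at desk scale with the shipped default corpus.
desk_run <- function() {
  cached_fixture("desk", run_all(default_config(seed = 1, profile = "desk")))
}

# Full pipeline run with the rms-boosts-voice-separation scenario corpus.
scenario_run <- function() {
  cached_fixture(
    "scenario",
    run_all(default_config(seed = 1, profile = "desk", corpus_type = "scenario"))
  )
}

# A very small but complete configuration for structural/determinism tests.
mini_config <- function(seed = 5) {
  cfg <- default_config(seed = seed, profile = "desk")
  cfg$corpus$n_sources <- 2L
  cfg$corpus$duration_s <- 2
  cfg$corpus$sample_rate <- 16000L
  cfg$design$excerpts_per_cell <- 4L
  cfg$design$durations_ms <- c(20, 50)
  cfg$filterbank$n_channels <- 30L
  cfg$filterbank$f_high <- 7000
  cfg$listener$n_participants <- list(PEAK = 3L, RMS = 3L)
  validate_config(cfg)
}

make_tone <- function(freq, fs, dur_s = 0.5, amp = 0.5) {
  amp * sin(2 * pi * freq * seq_len(round(dur_s * fs)) / fs)
}

make_clip <- function(samples, fs, label = "VOICE", source_id = "fix_00") {
  structure(
    list(samples = samples, sample_rate = fs, label = label, source_id = source_id),
    class = "audio_clip"
  )
}

# Independent PCA oracle: explicit eigendecomposition of the covariance or
# correlation matrix (no prcomp).
brute_pca <- function(x, mode = "CORRELATION") {
  x <- scale(x, center = TRUE, scale = (mode == "CORRELATION"))
  n <- nrow(x)
  cmat <- crossprod(x) / (n - 1)
  e <- eigen(cmat, symmetric = TRUE)
  keep <- seq_len(min(n - 1, ncol(x)))
  list(
    values = e$values,
    fractions = e$values / sum(e$values),
    scores = x %*% e$vectors,
    vectors = e$vectors
  )
}

# Independent distance oracle: explicit double loop over all pairs.
brute_distances <- function(scores, labels, k = 2) {
  n <- nrow(scores)
  within <- between <- numeric(n)
  for (i in seq_len(n)) {
    dw <- db <- c()
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((scores[i, 1:k] - scores[j, 1:k])^2))
      if (labels[i] == labels[j]) dw <- c(dw, d) else db <- c(db, d)
    }
    within[i] <- mean(dw)
    between[i] <- mean(db)
  }
  list(within = within, between = between)
}

# Tiny synthetic score geometry: three well-separated Gaussian clusters in
# 2-D, plus their summaries, for listener-model tests.
cluster_geometry <- function(n_per = 40, sep = 6, sd = 1, seed = 11) {
  set.seed(seed)
  centers <- rbind(
    VOICE = c(-sep, 0), MUSIC = c(sep / 2, sep), ESOUND = c(sep / 2, -sep)
  )
  labels <- rep(rownames(centers), each = n_per)
  scores <- centers[labels, ] + matrix(rnorm(2 * 3 * n_per, sd = sd), ncol = 2)
  rownames(scores) <- sprintf("G%03d", seq_along(labels))
  space <- structure(
    list(scores = scores, fitted_on = rownames(scores)),
    class = "feature_space"
  )
  list(
    scores = scores, labels = labels,
    summaries = summarize_categories(space, labels, n_components = 2),
    stimuli = tibble::tibble(
      stimulus_id = rownames(scores), label = labels,
      duration_ms = rep(c(20, 30, 50, 100, 200), length.out = length(labels)),
      normalization = "PEAK"
    )
  )
}
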