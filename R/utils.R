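#' Root-mean-square level of a signal
#'
#' @param x Numeric vector of samples.
#' @return A single non-negative number, `sqrt(mean(x^2))`.
#' @export
rms_level <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort("`x` must be a non-empty numeric vector.", class = "soundgate_parameter_error")
  }
  sqrt(mean(x^2))
}

#' Level in dB relative to full scale
#'
#' @param x Numeric vector of samples (full scale is amplitude 1).
#' @return `20 * log10(RMS(x))`; `-Inf` for an all-zero signal.
#' @export
dbfs_level <- function(x) {
  r <- rms_level(x)
  if (r == 0) -Inf else 20 * log10(r)
}

# Counter-based sub-seed derivation: a small multiplicative hash folded into
# [0, 2^31 - 2] so corpora are order-independent and every consumer of
# randomness gets its own stream from (master seed, stage/index counters).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (x in idx) {
    h <- (h * 69069 + as.double(x) + 12345) %% 2147483647
  }
  as.integer(h)
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_parameter <- function(msg) abort(msg, class = "soundgate_parameter_error")
stop_degenerate <- function(msg) abort(msg, class = "soundgate_degenerate_error")
stop_data <- function(msg) abort(msg, class = "soundgate_data_error")

#' The three category labels
#'
#' Every stimulus and every forced-choice response refers to one of three
#' sound categories: human voice, instrumental music, environmental sounds
#' ("ESounds").
#'
#' @return Character vector `c("VOICE", "MUSIC", "ESOUND")`.
#' @export
category_labels <- function() c("VOICE", "MUSIC", "ESOUND")

assert_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || !label %in% category_labels()) {
    stop_parameter(sprintf(
      "`label` must be one of %s.", paste(category_labels(), collapse = ", ")
    ))
  }
  label
}
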