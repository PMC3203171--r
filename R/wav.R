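# Minimal RIFF/WAVE reader and writer: mono, 16-bit integer PCM or 32-bit
# IEEE float. Enough to round-trip the corpora and stimuli this package
# produces; not a general-purpose WAV library (no multi-channel, no
# compressed formats, no cue/metadata chunks).

#' Write a mono WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @param bit_type `"pcm16"` (16-bit integer PCM) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, bit_type = c("pcm16", "float32")) {
  bit_type <- match.arg(bit_type)
  if (!is.numeric(samples) || length(samples) == 0L || any(!is.finite(samples))) {
    stop_parameter("`samples` must be a non-empty finite numeric vector.")
  }
  if (max(abs(samples)) > 1 + 1e-9) {
    stop_parameter("`samples` must lie in [-1, 1]; peak- or RMS-normalize first.")
  }
  sample_rate <- as.integer(sample_rate)
  n <- length(samples)
  if (bit_type == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    data_size <- 2L * n
  } else {
    fmt_code <- 3L; bits <- 32L
    data_size <- 4L * n
  }
  block_align <- bits %/% 8L
  byte_rate <- sample_rate * block_align

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(sample_rate, con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_type == "pcm16") {
    q <- as.integer(pmax(pmin(round(samples * 32767), 32767L), -32768L))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports the subset written by [write_wav()]: single-channel 16-bit PCM or
#' 32-bit float, with chunk skipping for files that carry extra chunks.
#'
#' @param path WAV file path.
#' @return A list with `samples` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (!identical(readChar(con, 4), "RIFF")) stop_data("Not a RIFF file.")
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop_data("Not a WAVE file.")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop_data("No data chunk found.")
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      n_chan <- readBin(con, "integer", size = 2, endian = "little")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16L) readBin(con, "raw", n = size - 16L)
      if (n_chan != 1L) stop_data("Only mono WAV files are supported.")
      fmt <- list(code = fmt_code, rate = rate, bits = bits)
    } else if (id == "data") {
      if (is.null(fmt)) stop_data("data chunk precedes fmt chunk.")
      if (fmt$code == 1L && fmt$bits == 16L) {
        raw <- readBin(con, "integer", n = size %/% 2L, size = 2,
                       signed = TRUE, endian = "little")
        samples <- raw / 32767
      } else if (fmt$code == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", n = size %/% 4L, size = 4,
                           endian = "little")
      } else {
        stop_data("Unsupported WAV encoding (need 16-bit PCM or 32-bit float).")
      }
      return(list(samples = samples, sample_rate = fmt$rate))
    } else {
      readBin(con, "raw", n = size + (size %% 2L))
    }
  }
}
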