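#' Construct a song recording
#'
#' The universal input object of the pipeline: a single-channel sampled
#' voltage trace with its sampling rate and a free-text genotype label.
#' Voltage units are arbitrary; every downstream threshold is relative
#' (slice levels and detection thresholds scale with the signal), so no
#' calibration is required.
#'
#' @param samples Numeric vector of voltage samples (finite, length >= 1).
#' @param sample_rate_hz Positive sampling rate in Hz; song analysis was
#'   designed around a nominal 10 kHz rate.
#' @param genotype Free-text genotype label attached to every derived record.
#' @param source Provenance string (file path or generator seed descriptor).
#' @return An object of class `song_recording`.
#' @export
song_recording <- function(samples, sample_rate_hz, genotype = "unknown",
                           source = "memory") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("a song recording needs at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      sample_rate_hz = as.numeric(sample_rate_hz),
      genotype = as.character(genotype)[1L],
      source = as.character(source)[1L]
    ),
    class = "song_recording"
  )
}

#' @export
print.song_recording <- function(x, ...) {
  cat(sprintf(
    "<song_recording> %s: %d samples @ %g Hz (%.2f s), source: %s\n",
    x$genotype, length(x$samples), x$sample_rate_hz,
    length(x$samples) / x$sample_rate_hz, x$source
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A [song_recording()].
#' @return Length of the trace in seconds.
#' @export
recording_duration <- function(recording) {
  length(recording$samples) / recording$sample_rate_hz
}

# --- WAV container ----------------------------------------------------------
# Minimal RIFF/WAVE support: mono, 16-bit integer PCM (format tag 1) or
# 32-bit IEEE float (format tag 3). Chunks other than fmt/data are skipped.

#' Read a mono WAV file
#'
#' Accepts 16-bit PCM and 32-bit IEEE float dialects. Integer PCM samples are
#' rescaled to `[-1, 1]`. Multichannel files are rejected: song recordings are
#' single-microphone traces and silently mixing channels would corrupt pulse
#' amplitudes.
#'
#' @param path Path to an existing WAV file.
#' @param genotype Genotype label attached to the recording.
#' @return A [song_recording()]; `sample_rate_hz` is taken from the header.
#'   A warning is raised when the rate differs from the nominal 10 kHz.
#' @export
read_wav <- function(path, genotype = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        tag = readBin(raw_fmt[1:2], "integer", 1L, 2L, signed = FALSE,
                      endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        rate = readBin(raw_fmt[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$tag == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", size / 2L, 2L, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$tag == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", size / 4L, 4L, endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format tag %d, %d bit); %s",
                     fmt$tag, fmt$bits,
                     "expected 16-bit PCM or 32-bit float"), call. = FALSE)
      }
    } else {
      # skip unknown chunk (word-aligned)
      seek(con, size + size %% 2L, origin = "current")
    }
    if (!is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples)) {
    stop("malformed WAV file: missing fmt or data chunk", call. = FALSE)
  }
  if (fmt$channels != 1L) {
    stop(sprintf("expected mono, got %d channels", fmt$channels),
         call. = FALSE)
  }
  if (fmt$rate != 10000L) {
    warning(sprintf("sample rate %d Hz differs from the nominal 10000 Hz",
                    fmt$rate), call. = FALSE)
  }
  song_recording(samples, fmt$rate, genotype = genotype, source = path)
}

#' Write a recording to a mono WAV file
#'
#' @param recording A [song_recording()].
#' @param path Output path.
#' @param bit_depth Either `16` (integer PCM; samples are clipped to
#'   `[-1, 1]` and quantized) or `32` (IEEE float, lossless).
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, bit_depth = 16L) {
  stopifnot(inherits(recording, "song_recording"))
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(16L, 32L)) {
    stop("bit_depth must be 16 (PCM) or 32 (float)", call. = FALSE)
  }
  x <- recording$samples
  n <- length(x)
  bytes_per <- bit_depth %/% 8L
  data_size <- n * bytes_per
  rate <- as.integer(round(recording$sample_rate_hz))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(if (bit_depth == 16L) 1L else 3L, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")  # mono
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")
  writeBin(bit_depth, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (bit_depth == 16L) {
    q <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    writeBin(q, con, 2L, endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4L, endian = "little")
  }
  invisible(path)
}
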