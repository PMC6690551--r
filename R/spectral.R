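#' Zero-phase band-pass filter
#'
#' Removes low-frequency drift (high-pass Butterworth of order 2 at
#' `band_low_hz`) and high-frequency noise (low-pass Butterworth of order 4,
#' with its corner placed 20% above `band_high_hz` so that the nominal band
#' stays flat within 1 dB up to 0.9 of the band edge), both applied
#' forward-backward for exactly zero phase. The mean is subtracted first, so
#' DC is removed exactly.
#'
#' @param recording A [song_recording()].
#' @param band_low_hz,band_high_hz Band edges (Hz), inside (0, Nyquist).
#' @return A filtered [song_recording()].
#' @export
bandpass_filter <- function(recording, band_low_hz = 1, band_high_hz = 500) {
  stopifnot(inherits(recording, "song_recording"))
  fs <- recording$sample_rate_hz
  nyq <- fs / 2
  if (band_low_hz <= 0 || band_high_hz <= band_low_hz ||
      band_high_hz >= nyq) {
    stop("need 0 < band_low_hz < band_high_hz < sample_rate/2",
         call. = FALSE)
  }
  x <- recording$samples - mean(recording$samples)
  hp <- signal::butter(2, band_low_hz / nyq, type = "high")
  lp <- signal::butter(4, min(band_high_hz * 1.2, 0.99 * nyq) / nyq,
                       type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  out <- recording
  out$samples <- as.numeric(y)
  out$source <- paste0(recording$source, " |bandpass[",
                       band_low_hz, ",", band_high_hz, "]")
  out
}

# Windowed periodogram of one segment on an N-point grid.
# The segment is mean-removed, Hann-tapered over its own extent, centered in
# the N-sample frame and zero-padded. Power is normalized by N * sum(w^2)
# (window correction), so the total over all N bins equals the
# window-weighted mean square of the mean-removed segment (Parseval).
segment_periodogram <- function(seg, n_fft) {
  L <- length(seg)
  if (L > n_fft) stop("segment longer than the FFT window", call. = FALSE)
  seg <- seg - mean(seg)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  y <- numeric(n_fft)
  start <- floor((n_fft - L) / 2)
  y[start + seq_len(L)] <- seg * w
  abs(stats::fft(y))^2 / (n_fft * sum(w^2))
}

new_power_spectrum <- function(power_full, n_fft, fs, n_segments,
                               noise_subtracted, band_low, band_high) {
  half <- n_fft %/% 2L
  freq <- (0:half) * fs / n_fft
  power <- power_full[1:(half + 1L)]
  in_band <- freq >= band_low & freq <= band_high
  peak_hz <- freq[in_band][which.max(power[in_band])]
  structure(
    list(freq_hz = freq, power = power, n_segments = n_segments,
         noise_subtracted = noise_subtracted, peak_hz = peak_hz,
         band_low_hz = band_low, band_high_hz = band_high),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d bins, %.6g Hz spacing, %d segment(s)%s; peak %.1f Hz\n",
    length(x$freq_hz), x$freq_hz[2] - x$freq_hz[1], x$n_segments,
    if (x$noise_subtracted) ", noise-subtracted" else "", x$peak_hz
  ))
  invisible(x)
}

#' Averaged power spectrum of detected pulses
#'
#' Each pulse window is centered in a zero-padded segment of
#' `fft_window_samples` samples (1024 by default: at 10 kHz the bin width is
#' 9.765625 Hz), mean-removed and Hann-tapered; per-pulse periodograms are
#' averaged across events. The maximal peak frequency is the bin of largest
#' averaged power within the analysis band, reported at full bin-center
#' precision. Each detected window is widened by 10 ms on both sides so the
#' pulse's sub-threshold ring-down is included (truncating it biases the
#' spectral peak low); windows longer than the segment are cropped around
#' the primary peak.
#'
#' @param recording The (typically band-passed) [song_recording()] the
#'   events were detected on.
#' @param events Tibble of pulse events from [analyze_pulses()], or any
#'   data frame with `window_start_s`/`window_end_s` (and optionally
#'   `primary_peak_s`).
#' @param config An [analysis_config()].
#' @return A `power_spectrum` (fields `freq_hz`, `power`, `n_segments`,
#'   `noise_subtracted`, `peak_hz`).
#' @export
pulse_spectrum <- function(recording, events, config = analysis_config()) {
  if (is.null(events) || nrow(events) == 0L) {
    stop("no pulses: cannot compute a pulse spectrum", call. = FALSE)
  }
  fs <- recording$sample_rate_hz
  n_fft <- config$fft_window_samples
  tail_margin_s <- 0.010
  acc <- numeric(n_fft)
  for (k in seq_len(nrow(events))) {
    win <- list(
      window_start_s = max(0, events$window_start_s[k] - tail_margin_s),
      window_end_s = events$window_end_s[k] + tail_margin_s
    )
    idx <- window_indices(recording, win)
    if (length(idx) > n_fft) {
      center <- if ("primary_peak_s" %in% names(events)) {
        as.integer(round(events$primary_peak_s[k] * fs)) + 1L
      } else {
        idx[ceiling(length(idx) / 2)]
      }
      i0 <- max(1L, center - n_fft %/% 2L)
      idx <- i0:(i0 + n_fft - 1L)
      idx <- idx[idx <= length(recording$samples)]
    }
    acc <- acc + segment_periodogram(recording$samples[idx], n_fft)
  }
  new_power_spectrum(acc / nrow(events), n_fft, fs, nrow(events),
                     noise_subtracted = FALSE,
                     config$band_low_hz, config$band_high_hz)
}

#' Power spectrum of song-free stretches
#'
#' Averaged periodogram over segments of the same length as the pulse
#' spectra, drawn from the parts of the recording at least 10 ms away from
#' every detected pulse window. Errors when less than 1 s of song-free
#' signal exists.
#'
#' @inheritParams pulse_spectrum
#' @return A `power_spectrum`.
#' @export
noise_spectrum <- function(recording, events, config = analysis_config()) {
  fs <- recording$sample_rate_hz
  n_fft <- config$fft_window_samples
  n <- length(recording$samples)
  pad <- as.integer(round(0.010 * fs))
  free <- rep(TRUE, n)
  if (!is.null(events) && nrow(events) > 0L) {
    for (k in seq_len(nrow(events))) {
      i0 <- max(1L, as.integer(floor(events$window_start_s[k] * fs)) + 1L - pad)
      i1 <- min(n, as.integer(ceiling(events$window_end_s[k] * fs)) + pad)
      free[i0:i1] <- FALSE
    }
  }
  if (sum(free) < fs) {
    stop("less than 1 s of song-free signal for the noise spectrum",
         call. = FALSE)
  }
  # chop free stretches into disjoint full-length segments
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  acc <- numeric(n_fft)
  m <- 0L
  for (j in which(r$values)) {
    s0 <- starts[j]
    while (s0 + n_fft - 1L <= ends[j]) {
      acc <- acc + segment_periodogram(recording$samples[s0:(s0 + n_fft - 1L)],
                                       n_fft)
      m <- m + 1L
      s0 <- s0 + n_fft
    }
  }
  if (m == 0L) {
    stop("no song-free segment of fft_window_samples length", call. = FALSE)
  }
  new_power_spectrum(acc / m, n_fft, fs, m, noise_subtracted = FALSE,
                     config$band_low_hz, config$band_high_hz)
}

#' Subtract a noise spectrum from a signal spectrum
#'
#' Bin-wise difference on identical frequency grids; bins where the noise
#' exceeds the signal are clamped to zero rather than going negative. The
#' maximal peak frequency is re-estimated from the subtracted spectrum.
#'
#' @param signal_spectrum,noise_spectrum `power_spectrum` objects on the
#'   same grid.
#' @return A noise-subtracted `power_spectrum`.
#' @export
subtract_noise <- function(signal_spectrum, noise_spectrum) {
  if (!isTRUE(all.equal(signal_spectrum$freq_hz, noise_spectrum$freq_hz))) {
    stop("frequency grids differ; cannot subtract", call. = FALSE)
  }
  out <- signal_spectrum
  out$power <- pmax(signal_spectrum$power - noise_spectrum$power, 0)
  out$noise_subtracted <- TRUE
  in_band <- out$freq_hz >= out$band_low_hz & out$freq_hz <= out$band_high_hz
  out$peak_hz <- out$freq_hz[in_band][which.max(out$power[in_band])]
  out
}

#' Class-stratified, noise-subtracted pulse spectra
#'
#' Computes separate power spectra for the pulses classified monocyclic and
#' polycyclic, each noise-subtracted against the song-free spectrum of the
#' same recording. A class with no pulses is omitted with a warning.
#'
#' @inheritParams pulse_spectrum
#' @return Named list with elements `monocyclic` and/or `polycyclic`, each a
#'   `power_spectrum`.
#' @export
stratified_spectra <- function(recording, events,
                               config = analysis_config()) {
  if (is.null(events) || nrow(events) == 0L) {
    stop("no pulses: cannot stratify spectra", call. = FALSE)
  }
  noise <- noise_spectrum(recording, events, config)
  out <- list()
  for (cls in c("monocyclic", "polycyclic")) {
    sub <- events[events$class == cls, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no ", cls, " pulses; entry omitted", call. = FALSE)
      next
    }
    out[[cls]] <- subtract_noise(pulse_spectrum(recording, sub, config),
                                 noise)
  }
  out
}
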