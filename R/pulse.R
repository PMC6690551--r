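#' Estimate the pre-pulse baseline voltage
#'
#' The baseline of a pulse is the mean output voltage over a window (3 s by
#' default) that immediately precedes its rising phase. Samples falling
#' inside previously detected pulse windows are excluded so that earlier
#' pulses in the bout do not bias the estimate. When less than the full
#' window of history exists, all available pre-onset samples are used; when
#' fewer than 50 ms remain, the estimator falls back to the recording-wide
#' median and flags this in the `"fallback"` attribute.
#'
#' @param recording A [song_recording()].
#' @param onset_s Onset time (s) of the pulse's rising phase.
#' @param window_s Length of the pre-onset averaging window (s).
#' @param exclude Optional data frame of intervals to exclude, with columns
#'   `window_start_s` and `window_end_s` (half-open).
#' @return Baseline voltage (scalar), with attribute `fallback` (logical).
#' @export
estimate_baseline <- function(recording, onset_s, window_s = 3,
                              exclude = NULL) {
  stopifnot(inherits(recording, "song_recording"))
  fs <- recording$sample_rate_hz
  n <- length(recording$samples)
  if (onset_s < 0 || onset_s > n / fs) {
    stop("onset_s lies outside the recording", call. = FALSE)
  }
  i_end <- as.integer(floor(onset_s * fs))          # pre-onset, half-open
  i_start <- max(1L, i_end - as.integer(round(window_s * fs)) + 1L)
  if (i_end < i_start) {
    out <- stats::median(recording$samples)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  idx <- i_start:i_end
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    span_start <- (i_start - 1L) / fs
    span_end <- i_end / fs
    ovl <- exclude$window_end_s > span_start &
      exclude$window_start_s < span_end
    if (any(ovl)) {
      drop <- rep(FALSE, length(idx))
      for (k in which(ovl)) {
        j0 <- max(i_start, as.integer(floor(exclude$window_start_s[k] * fs)) + 1L)
        j1 <- min(i_end, as.integer(ceiling(exclude$window_end_s[k] * fs)))
        if (j1 >= j0) drop[(j0 - i_start + 1L):(j1 - i_start + 1L)] <- TRUE
      }
      idx <- idx[!drop]
    }
  }
  if (length(idx) < 0.05 * fs) {  # under 50 ms of usable history
    out <- stats::median(recording$samples)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  out <- mean(recording$samples[idx])
  attr(out, "fallback") <- FALSE
  out
}

#' Detect provisional pulse windows
#'
#' Detection runs on a band-pass filtered trace (see [bandpass_filter()]).
#' The absolute threshold is `detection_noise_multiplier` (default 5) times
#' the median absolute deviation of the filtered signal -- robust to the
#' pulses themselves, which occupy a tiny fraction of a recording -- with a
#' small relative floor (`1e-4` of the maximal absolute deflection) so the
#' threshold stays positive on noise-free synthetic traces. Above-threshold
#' samples separated by lulls of at most 5 ms form one event; events closer
#' than 10 ms are merged (interpulse intervals of ~35 ms never merge);
#' events longer than `max_event_ms` are discarded as sustained oscillation,
#' which is how sine song is rejected. Window edges are padded by 1 ms.
#'
#' @param recording A band-pass filtered [song_recording()].
#' @param config An [analysis_config()].
#' @return Tibble with `window_start_s`, `window_end_s` (half-open,
#'   time-ordered, non-overlapping); zero rows on silence.
#' @export
detect_pulses <- function(recording, config = analysis_config()) {
  stopifnot(inherits(recording, "song_recording"))
  x <- recording$samples
  fs <- recording$sample_rate_hz
  peak_abs <- max(abs(x))
  empty <- tibble::tibble(window_start_s = numeric(),
                          window_end_s = numeric())
  if (peak_abs == 0) return(empty)

  thr <- max(config$detection_noise_multiplier * stats::mad(x),
             1e-4 * peak_abs)
  above <- which(abs(x) > thr)
  if (length(above) == 0L) return(empty)

  lull <- as.integer(round(0.005 * fs))    # 5 ms
  merge_gap <- as.integer(round(0.010 * fs))  # 10 ms
  pad <- as.integer(round(0.001 * fs))     # 1 ms edge margin

  brk <- which(diff(above) > lull)
  starts <- above[c(1L, brk + 1L)]
  ends <- above[c(brk, length(above))]

  # merge events whose edges are closer than 10 ms
  if (length(starts) > 1L) {
    keep_start <- starts[1L]
    out_s <- integer(0)
    out_e <- integer(0)
    cur_s <- starts[1L]
    cur_e <- ends[1L]
    for (k in 2L:length(starts)) {
      if (starts[k] - cur_e <= merge_gap) {
        cur_e <- ends[k]
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        cur_s <- starts[k]; cur_e <- ends[k]
      }
    }
    out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
    starts <- out_s; ends <- out_e
  }

  dur_ok <- (ends - starts + 1L) / fs * 1000 <= config$max_event_ms
  starts <- starts[dur_ok]
  ends <- ends[dur_ok]
  if (length(starts) == 0L) return(empty)

  tibble::tibble(
    window_start_s = pmax(0L, starts - 1L - pad) / fs,
    window_end_s = pmin(length(x), ends + pad) / fs
  )
}

#' Measure the peak height of a pulse
#'
#' The height is the distance between the largest positive-or-negative
#' deflection and the baseline; the primary peak is the earliest sample
#' attaining it (ties broken toward earlier times).
#'
#' @param recording A [song_recording()].
#' @param window Named list or one-row data frame with `window_start_s`,
#'   `window_end_s`.
#' @param baseline Baseline voltage.
#' @return List with `peak_height` and `primary_peak_s`.
#' @export
measure_peak_height <- function(recording, window, baseline) {
  idx <- window_indices(recording, window)
  if (length(idx) == 0L) stop("empty pulse window", call. = FALSE)
  d <- abs(recording$samples[idx] - baseline)
  j <- which.max(d)  # earliest maximum
  list(peak_height = d[j], primary_peak_s = (idx[j] - 1L) /
         recording$sample_rate_hz)
}

#' Count cycles of a pulse by the slice-level criterion
#'
#' The slice level is `slice_fraction` of the pulse's peak height above its
#' baseline. Local extrema of the absolute deflection within the window are
#' candidate peaks; every candidate exceeding the slice level is counted,
#' provided counted peaks are separated by at least 1 ms and by a
#' zero-crossing of the deflection or a dip below 50% of the smaller peak
#' (which prevents noise ripple riding on one lobe from being counted as
#' extra cycles). A pulse whose only counted deflection is the primary peak
#' is monocyclic; any additional counted (auxiliary) peak makes it
#' polycyclic.
#'
#' @param recording A [song_recording()].
#' @param window Named list or one-row data frame with `window_start_s`,
#'   `window_end_s`.
#' @param baseline Baseline voltage.
#' @param peak_height Peak height from [measure_peak_height()]; must be > 0.
#' @param slice_fraction Slice level as a fraction of peak height.
#' @return List with `cycle_count`, `pulse_class` (`"monocyclic"` or
#'   `"polycyclic"`), `peak_times_s` (ordered counted peak times) and
#'   `slice_level`.
#' @export
count_cycles <- function(recording, window, baseline, peak_height,
                         slice_fraction = 0.5) {
  if (peak_height <= 0) stop("peak_height must be positive", call. = FALSE)
  fs <- recording$sample_rate_hz
  idx <- window_indices(recording, window)
  d <- recording$samples[idx] - baseline
  slice_level <- slice_fraction * peak_height
  min_sep <- as.integer(round(0.001 * fs))  # 1 ms

  # partition into same-sign runs; zero samples break runs
  sgn <- sign(d)
  nonzero <- which(sgn != 0)
  counted_pos <- integer(0)
  counted_val <- numeric(0)
  if (length(nonzero) > 0L) {
    runs <- rle(sgn[nonzero])
    run_end <- cumsum(runs$lengths)
    run_start <- c(1L, utils::head(run_end, -1L) + 1L)
    for (r in seq_along(runs$lengths)) {
      seg_idx <- nonzero[run_start[r]:run_end[r]]
      seg <- abs(d[seg_idx])
      # local maxima within the run, strongest first
      cand <- local_maxima(seg)
      cand <- cand[seg[cand] > slice_level]
      if (length(cand) == 0L) next
      cand <- cand[order(-seg[cand], cand)]
      acc <- integer(0)
      for (ci in cand) {
        ok <- TRUE
        for (ai in acc) {
          gap <- abs(ci - ai)
          dip <- min(seg[min(ci, ai):max(ci, ai)])
          if (gap < min_sep || dip >= 0.5 * min(seg[ci], seg[ai])) {
            ok <- FALSE
            break
          }
        }
        if (ok) acc <- c(acc, ci)
      }
      counted_pos <- c(counted_pos, seg_idx[acc])
      counted_val <- c(counted_val, seg[acc])
    }
  }
  ord <- order(counted_pos)
  counted_pos <- counted_pos[ord]
  cycle_count <- length(counted_pos)
  if (cycle_count == 0L) {  # degenerate: peak itself at/below slice settings
    cycle_count <- 1L
    counted_pos <- idx[which.max(abs(d))] - idx[1L] + 1L
  }
  list(
    cycle_count = cycle_count,
    pulse_class = if (cycle_count == 1L) "monocyclic" else "polycyclic",
    peak_times_s = (idx[1L] + counted_pos - 2L) / fs,
    slice_level = slice_level
  )
}

local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  left <- c(TRUE, v[-1L] > v[-n])          # strictly rising from the left
  right <- c(v[-n] >= v[-1L], TRUE)        # non-rising to the right
  which(left & right)
}

window_indices <- function(recording, window) {
  fs <- recording$sample_rate_hz
  i0 <- max(1L, as.integer(floor(window$window_start_s * fs)) + 1L)
  i1 <- min(length(recording$samples),
            as.integer(ceiling(window$window_end_s * fs)))
  if (i1 < i0) integer(0) else i0:i1
}

#' Detect, measure and classify every pulse in a recording
#'
#' Full pulse-analysis stage: band-pass the trace, detect pulse windows,
#' estimate each pulse's baseline from the preceding signal (excluding
#' already-detected pulse windows), measure peak heights, and apply the
#' slice-level cycle-count criterion. Classification runs on the band-passed
#' trace, so DC offsets and low-frequency drift never reach the slice
#' comparison. Zero-height events are rejected.
#'
#' @param recording A raw [song_recording()].
#' @param config An [analysis_config()].
#' @return Tibble of pulse events: `primary_peak_s`, `baseline`,
#'   `peak_height`, `cycle_count`, `class`, `slice_level`, `window_start_s`,
#'   `window_end_s`, plus a `peak_times` list-column of counted peak times.
#' @export
analyze_pulses <- function(recording, config = analysis_config()) {
  filtered <- bandpass_filter(recording, config$band_low_hz,
                              config$band_high_hz)
  windows <- detect_pulses(filtered, config)
  empty <- tibble::tibble(
    primary_peak_s = numeric(), baseline = numeric(),
    peak_height = numeric(), cycle_count = integer(), class = character(),
    slice_level = numeric(), window_start_s = numeric(),
    window_end_s = numeric(), peak_times = list()
  )
  if (nrow(windows) == 0L) return(empty)

  rows <- vector("list", nrow(windows))
  for (k in seq_len(nrow(windows))) {
    win <- windows[k, ]
    prior <- windows[seq_len(k - 1L), , drop = FALSE]
    base <- estimate_baseline(filtered, win$window_start_s,
                              config$baseline_window_s, exclude = prior)
    pk <- measure_peak_height(filtered, win, base)
    if (pk$peak_height <= 0) next
    cc <- count_cycles(filtered, win, base, pk$peak_height,
                       config$slice_fraction)
    rows[[k]] <- tibble::tibble(
      primary_peak_s = pk$primary_peak_s,
      baseline = as.numeric(base),
      peak_height = pk$peak_height,
      cycle_count = cc$cycle_count,
      class = cc$pulse_class,
      slice_level = cc$slice_level,
      window_start_s = win$window_start_s,
      window_end_s = win$window_end_s,
      peak_times = list(cc$peak_times_s)
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Summarize pulse classification
#'
#' @param events Tibble of pulse events from [analyze_pulses()].
#' @return List with `n_pulses`, `n_polycyclic`, `percent_polycyclic`
#'   (`NA` when there are no pulses, not 0) and `cycle_histogram`
#'   (named counts per cycle number).
#' @export
summarize_classification <- function(events) {
  n <- nrow(events)
  if (n == 0L) {
    return(list(n_pulses = 0L, n_polycyclic = 0L,
                percent_polycyclic = NA_real_,
                cycle_histogram = integer(0)))
  }
  n_poly <- sum(events$class == "polycyclic")
  hist <- table(events$cycle_count)
  list(
    n_pulses = n,
    n_polycyclic = n_poly,
    percent_polycyclic = 100 * n_poly / n,
    cycle_histogram = stats::setNames(as.integer(hist), names(hist))
  )
}
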