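#' Genotype presets for the synthetic song generator
#'
#' Two parameterizations emulating the song phenotypes the pipeline was built
#' to discriminate. `"wildtype"` produces exclusively monocyclic pulses with a
#' 232 Hz carrier and interpulse intervals around 35 ms. `"cro"` emulates the
#' croaker/Camta loss-of-function phenotype: 35% of pulses polycyclic (two
#' cycles ~65%, three ~34.5%, four ~0.5% of polycyclic pulses), a monocyclic
#' carrier of 313 Hz, a polycyclic carrier of 350 Hz, and prolonged IPIs
#' (40 +/- 4 ms).
#'
#' @param name One of `"wildtype"`, `"cro"`.
#' @return A list of generator parameters (class `genotype_song_params`):
#'   `ipi_mean_ms`, `ipi_sd_ms`, `pulse_carrier_hz`, `polycyclic_carrier_hz`,
#'   `polycyclic_fraction`, `cycle_mixture` (named probabilities for 2, 3 and
#'   4 cycles, conditional on polycyclic), `pulse_amplitude`, `noise_sd`,
#'   `bout_length_pulses`, `interbout_gap_s`, `sine_song` (NULL = off),
#'   `baseline_offset`.
#' @export
genotype_preset <- function(name) {
  presets <- list(
    wildtype = genotype_song_params(
      ipi_mean_ms = 35, ipi_sd_ms = 3,
      pulse_carrier_hz = 232, polycyclic_carrier_hz = 232,
      polycyclic_fraction = 0,
      cycle_mixture = c(`2` = 0.65, `3` = 0.345, `4` = 0.005)
    ),
    cro = genotype_song_params(
      ipi_mean_ms = 40, ipi_sd_ms = 4,
      pulse_carrier_hz = 313, polycyclic_carrier_hz = 350,
      polycyclic_fraction = 0.35,
      cycle_mixture = c(`2` = 0.65, `3` = 0.345, `4` = 0.005)
    )
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  out <- presets[[name]]
  attr(out, "preset") <- name
  out
}

#' Construct generator parameters
#'
#' See [genotype_preset()] for the two standard parameterizations. Defaults
#' shared by all presets: unit pulse amplitude with additive white noise of
#' SD 0.1 (peak-amplitude SNR 10), Poisson bouts of mean 25 pulses separated
#' by 0.5 s of silence, no sine song, zero DC offset.
#'
#' @param ipi_mean_ms,ipi_sd_ms Normal IPI distribution (ms), truncated below
#'   at 15 ms so that physically ~5-18 ms wide pulses never overlap.
#' @param pulse_carrier_hz Carrier (Hz) of monocyclic pulses.
#' @param polycyclic_carrier_hz Carrier (Hz) of polycyclic pulses.
#' @param polycyclic_fraction Probability that a pulse is polycyclic.
#' @param cycle_mixture Named probability vector over cycle counts
#'   (conditional on polycyclic); must sum to 1.
#' @param pulse_amplitude Peak absolute amplitude of each pulse.
#' @param noise_sd SD of additive white recording noise.
#' @param bout_length_pulses Mean pulses per bout (Poisson, truncated >= 2);
#'   0 disables pulses entirely.
#' @param interbout_gap_s Silent gap between bouts (s).
#' @param sine_song `NULL`, or `list(carrier_hz, amplitude, duration_s)`;
#'   sine-song segments are placed in inter-bout gaps.
#' @param baseline_offset Constant DC offset added to the trace.
#' @return A `genotype_song_params` list.
#' @export
genotype_song_params <- function(ipi_mean_ms, ipi_sd_ms,
                                 pulse_carrier_hz, polycyclic_carrier_hz,
                                 polycyclic_fraction,
                                 cycle_mixture = c(`2` = 0.65, `3` = 0.345,
                                                   `4` = 0.005),
                                 pulse_amplitude = 1,
                                 noise_sd = 0.1,
                                 bout_length_pulses = 25,
                                 interbout_gap_s = 0.5,
                                 sine_song = NULL,
                                 baseline_offset = 0) {
  if (ipi_mean_ms <= 0) stop("ipi_mean_ms must be positive", call. = FALSE)
  if (polycyclic_fraction < 0 || polycyclic_fraction > 1) {
    stop("polycyclic_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cycle_mixture) - 1) > 1e-8) {
    stop("cycle_mixture probabilities must sum to 1", call. = FALSE)
  }
  structure(
    list(
      ipi_mean_ms = ipi_mean_ms, ipi_sd_ms = ipi_sd_ms,
      pulse_carrier_hz = pulse_carrier_hz,
      polycyclic_carrier_hz = polycyclic_carrier_hz,
      polycyclic_fraction = polycyclic_fraction,
      cycle_mixture = cycle_mixture,
      pulse_amplitude = pulse_amplitude,
      noise_sd = noise_sd,
      bout_length_pulses = bout_length_pulses,
      interbout_gap_s = interbout_gap_s,
      sine_song = sine_song,
      baseline_offset = baseline_offset
    ),
    class = "genotype_song_params"
  )
}

#' Synthesize a single song pulse
#'
#' The pulse model is a damped oscillation: a carrier sinusoid under a
#' piecewise envelope with a flat plateau spanning the requested number of
#' cycles, an initial decay to 20% of peak within one half-period, and a
#' slower ring-down losing 35% per half-period, truncated at 5% of peak.
#' Under the slice criterion at 50% (and at 60%), the number of half-period
#' lobes exceeding the slice level equals `cycle_count` exactly in the
#' noise-free case, before and after band-pass filtering; sub-slice ring-down
#' lobes keep the power spectrum centered on the carrier, as in recorded
#' pulses.
#'
#' @param cycle_count Integer >= 1; number of lobes that exceed the slice.
#' @param carrier_hz Carrier frequency (must be below Nyquist).
#' @param amplitude Peak absolute value of the returned waveform.
#' @param sample_rate_hz Sampling rate (Hz).
#' @return Numeric sample vector (all zero when `amplitude` is 0).
#' @export
make_pulse <- function(cycle_count, carrier_hz, amplitude, sample_rate_hz) {
  cycle_count <- as.integer(cycle_count)
  if (is.na(cycle_count) || cycle_count < 1L) {
    stop("cycle_count must be an integer >= 1", call. = FALSE)
  }
  if (carrier_hz >= sample_rate_hz / 2) {
    stop("carrier_hz must be below the Nyquist frequency", call. = FALSE)
  }
  drop_ratio <- 0.20    # envelope after the first off-plateau half-period
  ring_ratio <- 0.65    # per-half-period decay of the ring-down
  trunc_at <- 0.05      # envelope truncation

  half_period <- 1 / (2 * carrier_hz)
  plateau <- (cycle_count - 1) / (4 * carrier_hz)
  tau_drop <- -half_period / log(drop_ratio)
  tau_ring <- -half_period / log(ring_ratio)
  half_width <- plateau + half_period + tau_ring * log(drop_ratio / trunc_at)

  tt <- seq(-half_width, half_width, by = 1 / sample_rate_hz)
  u <- pmax(abs(tt) - plateau, 0)
  env <- ifelse(u <= half_period,
                exp(-u / tau_drop),
                drop_ratio * exp(-(u - half_period) / tau_ring))
  phase <- if (cycle_count %% 2L == 1L) {
    cos(2 * pi * carrier_hz * tt)  # odd lobe count: symmetric about center
  } else {
    # even lobe count: antisymmetric; tilt the trailing half by 5% so the
    # first central lobe is the unambiguous primary peak (filtering and
    # sampling cannot flip the argmax between two exactly equal lobes)
    sin(2 * pi * carrier_hz * tt) * ifelse(tt > 0, 0.95, 1)
  }
  x <- env * phase
  if (amplitude == 0) return(numeric(length(x)))
  amplitude * x / max(abs(x))
}

#' Generate a synthetic courtship song with ground truth
#'
#' Places damped-oscillation pulses in Poisson-length bouts, with
#' peak-to-peak interpulse intervals drawn from a truncated normal
#' distribution, per-pulse class and cycle count drawn from the preset
#' mixture, then adds white noise and a DC offset. All draws use a single
#' pseudo-random stream seeded once per call, in fixed order (bout lengths
#' and IPIs and per-pulse classes as the song is laid out left to right, then
#' noise), so identical `(params, duration_s, seed)` yield identical output.
#' The global RNG state is left untouched.
#'
#' The song starts after 3.2 s of lead-in (so even the first pulse has the
#' full 3 s baseline window available), and ground truth records every drawn
#' value. The true primary-peak time of each pulse is the time of the
#' earliest maximal absolute sample of its inserted waveform, the same
#' convention the analyzer uses.
#'
#' @param params A [genotype_song_params()] (or [genotype_preset()] result).
#' @param duration_s Total recording length in seconds (> 0).
#' @param seed Integer seed.
#' @param sample_rate_hz Sampling rate; defaults to the nominal 10 kHz.
#' @return A list with `recording` (a [song_recording()]) and `truth`, itself
#'   a list of `pulses` (tibble: onset_s, peak_s, cycle_count, class,
#'   carrier_hz, bout_id) and `bouts` (tibble: bout_id, start_s, end_s).
#' @export
generate_song <- function(params, duration_s, seed,
                          sample_rate_hz = 10000) {
  stopifnot(inherits(params, "genotype_song_params"))
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  fs <- sample_rate_hz
  n_total <- as.integer(round(duration_s * fs))

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)

  x <- numeric(n_total)
  lead_in_s <- 3.2
  tail_margin_s <- 0.1
  ipi_floor_ms <- 15

  pulses <- list()
  bouts <- list()
  bout_id <- 0L
  t_cursor <- lead_in_s

  if (params$bout_length_pulses > 0) {
    repeat {
      n_pulses <- max(2L, stats::rpois(1L, params$bout_length_pulses))
      peak_times <- t_cursor
      for (k in seq_len(n_pulses - 1L)) {
        repeat {
          ipi <- stats::rnorm(1L, params$ipi_mean_ms, params$ipi_sd_ms)
          if (ipi >= ipi_floor_ms) break
        }
        peak_times <- c(peak_times, peak_times[length(peak_times)] + ipi / 1000)
      }
      peak_times <- peak_times[peak_times < duration_s - tail_margin_s]
      if (length(peak_times) < 1L) break
      bout_id <- bout_id + 1L

      for (pt in peak_times) {
        is_poly <- stats::runif(1L) < params$polycyclic_fraction
        if (is_poly) {
          cyc <- as.integer(sample(names(params$cycle_mixture), 1L,
                                   prob = params$cycle_mixture))
          carrier <- params$polycyclic_carrier_hz
        } else {
          cyc <- 1L
          carrier <- params$pulse_carrier_hz
        }
        wave <- make_pulse(cyc, carrier, params$pulse_amplitude, fs)
        prim <- which.max(abs(wave))[1L]
        peak_idx <- as.integer(round(pt * fs)) + 1L
        start_idx <- peak_idx - prim + 1L
        idx <- seq(start_idx, start_idx + length(wave) - 1L)
        keep <- idx >= 1L & idx <= n_total
        x[idx[keep]] <- x[idx[keep]] + wave[keep]
        pulses[[length(pulses) + 1L]] <- list(
          onset_s = (start_idx - 1L) / fs,
          peak_s = (peak_idx - 1L) / fs,
          cycle_count = cyc,
          class = if (is_poly) "polycyclic" else "monocyclic",
          carrier_hz = carrier,
          bout_id = bout_id
        )
      }
      bouts[[bout_id]] <- list(
        bout_id = bout_id,
        start_s = peak_times[1L],
        end_s = peak_times[length(peak_times)]
      )
      t_cursor <- peak_times[length(peak_times)] + params$interbout_gap_s
      if (t_cursor >= duration_s - tail_margin_s) break
    }
  }

  # sine-song segments fill inter-bout silence (minus a 50 ms guard)
  if (!is.null(params$sine_song)) {
    ss <- params$sine_song
    guard <- 0.05
    gaps <- sine_gaps(bouts, duration_s, guard)
    tt_all <- seq_len(n_total) / fs
    for (g in seq_len(nrow(gaps))) {
      i0 <- max(1L, as.integer(ceiling(gaps$start[g] * fs)))
      i1 <- min(n_total, as.integer(floor(gaps$end[g] * fs)))
      if (i1 <= i0) next
      seg_t <- tt_all[i0:i1] - tt_all[i0]
      ramp <- pmin(1, pmin(seg_t, rev(seg_t)) / 0.02)  # 20 ms on/off ramps
      x[i0:i1] <- x[i0:i1] +
        ss$amplitude * ramp * sin(2 * pi * ss$carrier_hz * seg_t)
    }
  }

  if (params$noise_sd > 0) {
    x <- x + stats::rnorm(n_total, 0, params$noise_sd)
  }
  x <- x + params$baseline_offset

  truth_pulses <- if (length(pulses) > 0L) {
    do.call(rbind, lapply(pulses, function(p) {
      tibble::tibble(onset_s = p$onset_s, peak_s = p$peak_s,
                     cycle_count = p$cycle_count, class = p$class,
                     carrier_hz = p$carrier_hz, bout_id = p$bout_id)
    }))
  } else {
    tibble::tibble(onset_s = numeric(), peak_s = numeric(),
                   cycle_count = integer(), class = character(),
                   carrier_hz = numeric(), bout_id = integer())
  }
  truth_bouts <- if (length(bouts) > 0L) {
    do.call(rbind, lapply(bouts, function(b) {
      tibble::tibble(bout_id = b$bout_id, start_s = b$start_s, end_s = b$end_s)
    }))
  } else {
    tibble::tibble(bout_id = integer(), start_s = numeric(), end_s = numeric())
  }

  rec <- song_recording(
    x, fs,
    genotype = attr(params, "preset", exact = TRUE) %||% "synthetic",
    source = sprintf("generate_song(seed=%d)", as.integer(seed))
  )
  list(recording = rec, truth = list(pulses = truth_pulses, bouts = truth_bouts))
}

# silent intervals between bouts (plus lead-in/tail), guarded
sine_gaps <- function(bouts, duration_s, guard) {
  if (length(bouts) == 0L) {
    return(data.frame(start = 0, end = duration_s))
  }
  starts <- vapply(bouts, `[[`, numeric(1), "start_s")
  ends <- vapply(bouts, `[[`, numeric(1), "end_s")
  # bout audio extends ~15 ms beyond the outer peaks; widen the guard
  edge <- guard + 0.02
  gap_start <- c(0, ends + edge)
  gap_end <- c(starts - edge, duration_s)
  keep <- gap_end - gap_start > 0.1
  data.frame(start = gap_start[keep], end = gap_end[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
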