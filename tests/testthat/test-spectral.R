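test_that("the band-pass filter removes DC and keeps the song band", {
  fs <- 10000
  tt <- seq(0, 2, by = 1 / fs)

  dc <- song_recording(rep(1, 2 * fs), fs)
  out <- bandpass_filter(dc)
  expect_lt(max(abs(out$samples)), 1e-9)

  mid <- function(x) x[(length(x) / 4):(3 * length(x) / 4)]
  tone <- song_recording(sin(2 * pi * 234 * tt), fs)
  expect_lt(abs(max(abs(mid(bandpass_filter(tone)$samples))) - 1), 0.01)

  hi <- song_recording(sin(2 * pi * 2000 * tt), fs)
  expect_lt(max(abs(mid(bandpass_filter(hi)$samples))), 0.1)  # >= 20 dB down

  expect_error(bandpass_filter(tone, 0, 500), "band_low_hz")
  expect_error(bandpass_filter(tone, 1, 6000), "band_low_hz")
})

test_that("a pure tone filling the window peaks at its own bin", {
  fs <- 10000
  x <- sin(2 * pi * 312.5 * (0:10239) / fs)
  rec <- song_recording(x, fs)
  ev <- tibble::tibble(window_start_s = 0.2, window_end_s = 0.2 + 1024 / fs)
  spec <- pulse_spectrum(rec, ev, analysis_config())
  expect_equal(spec$peak_hz, 312.5)
  expect_equal(spec$freq_hz[2] - spec$freq_hz[1], 10000 / 1024)
})

test_that("peak frequency obeys bin quantization for arbitrary tones", {
  fs <- 10000
  n_fft <- 1024L
  grid <- (0:(n_fft / 2)) * fs / n_fft
  set.seed(31)
  for (f in runif(20, 100, 450)) {
    x <- sin(2 * pi * f * (0:(n_fft * 3 - 1)) / fs)
    rec <- song_recording(x, fs)
    # window crop margins keep the segment a full n_fft of pure tone
    ev <- tibble::tibble(window_start_s = 0.12,
                         window_end_s = 0.12 + n_fft / fs)
    spec <- suppressWarnings(pulse_spectrum(rec, ev, analysis_config()))
    expect_equal(spec$peak_hz, grid[which.min(abs(grid - f))],
                 info = sprintf("f = %.3f", f))
  }
})

test_that("the windowed periodogram satisfies Parseval with window correction", {
  set.seed(32)
  seg <- rnorm(700)
  p <- pulsesong:::segment_periodogram(seg, 1024L)
  w <- 0.5 * (1 - cos(2 * pi * seq_along(seg) / (length(seg) + 1)))
  y <- (seg - mean(seg)) * w
  expect_equal(sum(p), sum(y^2) / sum(w^2), tolerance = 1e-9)
})

test_that("the noise spectrum of white noise is flat across the band", {
  set.seed(33)
  rec <- song_recording(rnorm(60 * 10000), 10000)
  ns <- noise_spectrum(rec, NULL, analysis_config())
  expect_gt(ns$n_segments, 500)
  low <- mean(ns$power[ns$freq_hz >= 50 & ns$freq_hz <= 200])
  high <- mean(ns$power[ns$freq_hz >= 250 & ns$freq_hz <= 450])
  expect_lt(abs(low / high - 1), 0.05)
})

test_that("silence yields an all-zero noise spectrum and short traces error", {
  rec <- song_recording(numeric(30000), 10000)
  ns <- noise_spectrum(rec, NULL, analysis_config())
  expect_true(all(ns$power == 0))

  short <- song_recording(numeric(5000), 10000)
  expect_error(noise_spectrum(short, NULL, analysis_config()),
               "less than 1 s")
})

test_that("noise subtraction clamps at zero and tracks provenance", {
  set.seed(34)
  rec <- song_recording(rnorm(30000), 10000)
  s <- noise_spectrum(rec, NULL, analysis_config())
  zero <- subtract_noise(s, s)
  expect_true(all(zero$power == 0))
  expect_true(zero$noise_subtracted)

  bigger <- s
  bigger$power <- s$power * 2
  clamped <- subtract_noise(s, bigger)
  expect_true(all(clamped$power == 0))

  other <- s
  other$freq_hz <- s$freq_hz + 1
  expect_error(subtract_noise(s, other), "grids differ")
})

test_that("averaging pulse spectra is linear over event subsets", {
  p <- genotype_preset("cro")
  p$noise_sd <- 0
  song <- generate_song(p, 12, seed = 9)
  filtered <- bandpass_filter(song$recording)
  events <- analyze_pulses(song$recording)
  n <- nrow(events)
  a <- events[seq_len(n %/% 3), ]
  b <- events[(n %/% 3 + 1):n, ]
  spec_a <- pulse_spectrum(filtered, a)
  spec_b <- pulse_spectrum(filtered, b)
  spec_all <- pulse_spectrum(filtered, events)
  weighted <- (spec_a$power * nrow(a) + spec_b$power * nrow(b)) / n
  expect_equal(weighted, spec_all$power, tolerance = 1e-12)
})

test_that("stratified spectra separate the two carriers of cro-like song", {
  p <- genotype_preset("cro")
  p$noise_sd <- 0
  song <- generate_song(p, 25, seed = 10)
  filtered <- bandpass_filter(song$recording)
  events <- analyze_pulses(song$recording)
  strat <- stratified_spectra(filtered, events)
  expect_named(strat, c("monocyclic", "polycyclic"))
  expect_equal(strat$monocyclic$peak_hz, 312.5)
  expect_equal(strat$polycyclic$peak_hz, 351.5625)
  expect_true(strat$monocyclic$noise_subtracted)

  # polycyclic pulses carry relatively more high-frequency shoulder
  rel_high <- function(s) {
    sum(s$power[s$freq_hz > 400 & s$freq_hz <= 500]) / max(s$power)
  }
  expect_gt(rel_high(strat$polycyclic), rel_high(strat$monocyclic))
})

test_that("a song without polycyclic pulses omits that stratum with a warning", {
  p <- genotype_preset("wildtype")
  p$noise_sd <- 0
  song <- generate_song(p, 12, seed = 12)
  filtered <- bandpass_filter(song$recording)
  events <- analyze_pulses(song$recording)
  expect_warning(strat <- stratified_spectra(filtered, events),
                 "no polycyclic")
  expect_named(strat, "monocyclic")
})

test_that("peak frequency is invariant to amplitude scaling", {
  p <- genotype_preset("cro")
  p$noise_sd <- 0
  song <- generate_song(p, 12, seed = 13)
  events <- analyze_pulses(song$recording)
  filtered <- bandpass_filter(song$recording)
  scaled <- filtered
  scaled$samples <- scaled$samples * 41.7
  expect_equal(pulse_spectrum(scaled, events)$peak_hz,
               pulse_spectrum(filtered, events)$peak_hz)
})
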