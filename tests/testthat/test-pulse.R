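test_that("estimate_baseline averages the pre-onset window", {
  fs <- 10000
  const <- song_recording(rep(0.37, 5 * fs), fs)
  expect_equal(as.numeric(estimate_baseline(const, 4)), 0.37)

  offset <- song_recording(rep(0.5, 10 * fs), fs)
  b <- estimate_baseline(offset, 5)
  expect_equal(as.numeric(b), 0.5)
  expect_false(attr(b, "fallback"))

  # onset at the very start: falls back to the recording-wide median
  b0 <- estimate_baseline(offset, 0)
  expect_true(attr(b0, "fallback"))
  expect_equal(as.numeric(b0), 0.5)

  expect_error(estimate_baseline(const, 99), "outside")
})

test_that("baselines recover a DC offset on generated songs", {
  p <- genotype_preset("wildtype")
  p$baseline_offset <- 0.2
  p$noise_sd <- 0.01
  song <- generate_song(p, 20, seed = 3)
  tp <- song$truth$pulses
  late <- tp[tp$onset_s >= 3, ]
  windows <- tibble::tibble(window_start_s = tp$onset_s,
                            window_end_s = tp$onset_s +
                              (tp$peak_s - tp$onset_s) * 2)
  for (k in sample(nrow(late), 20)) {
    b <- estimate_baseline(song$recording, late$onset_s[k], 3,
                           exclude = windows)
    expect_lt(abs(as.numeric(b) - 0.2), 0.005)
  }
})

test_that("detection finds every true pulse and nothing else", {
  p <- genotype_preset("wildtype")
  p$noise_sd <- 0
  song <- generate_song(p, 15, seed = 2)
  filtered <- bandpass_filter(song$recording)
  windows <- detect_pulses(filtered)
  tp <- song$truth$pulses
  expect_gte(nrow(tp), 100)
  expect_equal(nrow(windows), nrow(tp))
  # each window contains exactly its true peak
  expect_true(all(tp$peak_s >= windows$window_start_s &
                    tp$peak_s < windows$window_end_s))
  expect_false(is.unsorted(windows$window_start_s))
  expect_true(all(windows$window_end_s[-nrow(windows)] <=
                    windows$window_start_s[-1]))
})

test_that("pure noise and silence yield no detections", {
  p <- genotype_preset("wildtype")
  p$bout_length_pulses <- 0
  p$noise_sd <- 0.01
  song <- generate_song(p, 60, seed = 4)
  filtered <- bandpass_filter(song$recording)
  expect_equal(nrow(detect_pulses(filtered)), 0L)

  silent <- song_recording(numeric(10000), 10000)
  expect_equal(nrow(detect_pulses(silent)), 0L)
})

test_that("sustained sine song does not trigger pulse detection", {
  p <- genotype_preset("wildtype")
  p$bout_length_pulses <- 0
  p$noise_sd <- 0.005
  p$sine_song <- list(carrier_hz = 150, amplitude = 0.3, duration_s = 10)
  song <- generate_song(p, 30, seed = 5)
  filtered <- bandpass_filter(song$recording)
  expect_equal(nrow(detect_pulses(filtered)), 0L)
})

test_that("peak height is the largest deflection of either polarity", {
  fs <- 10000
  x <- numeric(1000)
  x[300] <- 1.2
  rec <- song_recording(x, fs)
  win <- list(window_start_s = 0.02, window_end_s = 0.05)
  pk <- measure_peak_height(rec, win, 0)
  expect_equal(pk$peak_height, 1.2)
  expect_equal(pk$primary_peak_s, 299 / fs)

  x2 <- numeric(1000)
  x2[300] <- 0.8
  x2[400] <- -1.0
  rec2 <- song_recording(x2, fs)
  pk2 <- measure_peak_height(rec2, win, 0)
  expect_equal(pk2$peak_height, 1.0)
  expect_equal(pk2$primary_peak_s, 399 / fs)  # the negative peak wins

  flat <- song_recording(rep(0.4, 1000), fs)
  pk3 <- measure_peak_height(flat, win, 0.4)
  expect_equal(pk3$peak_height, 0)
  expect_equal(pk3$primary_peak_s, win$window_start_s)
})

test_that("the slice criterion separates mono- from polycyclic pulses", {
  single <- lobe_recording(1)
  cc <- count_cycles(single$recording, single$window, 0, 1, 0.5)
  expect_equal(cc$cycle_count, 1L)
  expect_equal(cc$pulse_class, "monocyclic")

  cases <- list(
    list(heights = c(1, 0.60), slice = 0.5, expected = 2L),
    list(heights = c(1, 0.45), slice = 0.5, expected = 1L),
    list(heights = c(1, 0.55), slice = 0.5, expected = 2L),
    list(heights = c(1, 0.55), slice = 0.6, expected = 1L),  # stringent
    list(heights = c(0.7, 1, 0.7, 0.3), slice = 0.5, expected = 3L)
  )
  for (cs in cases) {
    fx <- lobe_recording(cs$heights)
    cc <- count_cycles(fx$recording, fx$window, 0, fx$peak_height, cs$slice)
    expect_equal(cc$cycle_count, cs$expected,
                 info = paste(cs$heights, collapse = "/"))
    expect_equal(cc$slice_level, cs$slice * fx$peak_height)
    expect_length(cc$peak_times_s, cs$expected)
  }
})

test_that("generated three-cycle pulses are counted with half-period spacing", {
  fs <- 10000
  wave <- make_pulse(3, 350, 1, fs)
  rec <- song_recording(c(numeric(500), wave, numeric(500)), fs)
  win <- list(window_start_s = 0.045,
              window_end_s = (1000 + length(wave)) / fs)
  cc <- count_cycles(rec, win, 0, 1, 0.5)
  expect_equal(cc$cycle_count, 3L)
  spacing <- diff(cc$peak_times_s) * 1000
  expect_true(all(abs(spacing - 1000 / (2 * 350)) < 0.25))
})

test_that("classification is invariant to gain, DC, and sign", {
  p <- genotype_preset("cro")
  p$noise_sd <- 0
  song <- generate_song(p, 15, seed = 6)
  base_events <- analyze_pulses(song$recording)
  expect_gt(nrow(base_events), 50)

  transform_and_analyze <- function(f) {
    rec <- song$recording
    rec$samples <- f(rec$samples)
    analyze_pulses(rec)
  }
  for (f in list(function(x) 3.7 * x,
                 function(x) x + 0.9,
                 function(x) -x)) {
    ev <- transform_and_analyze(f)
    expect_equal(ev$cycle_count, base_events$cycle_count)
    expect_equal(ev$class, base_events$class)
  }
})

test_that("raising the slice fraction never increases cycle counts", {
  p <- genotype_preset("cro")
  p$noise_sd <- 0
  song <- generate_song(p, 15, seed = 6)
  ev50 <- analyze_pulses(song$recording, analysis_config(slice_fraction = 0.5))
  ev60 <- analyze_pulses(song$recording, analysis_config(slice_fraction = 0.6))
  expect_equal(nrow(ev50), nrow(ev60))  # detection is slice-independent
  expect_true(all(ev60$cycle_count <= ev50$cycle_count))
})

test_that("classification summaries compute the polycyclic percentage", {
  ev <- tibble::tibble(class = rep("monocyclic", 10), cycle_count = 1L)
  s <- summarize_classification(ev)
  expect_equal(s$percent_polycyclic, 0)

  ev2 <- tibble::tibble(
    class = c(rep("monocyclic", 7), rep("polycyclic", 3)),
    cycle_count = c(rep(1L, 7), 2L, 2L, 3L)
  )
  s2 <- summarize_classification(ev2)
  expect_equal(s2$percent_polycyclic, 30)
  expect_equal(s2$cycle_histogram, c(`1` = 7L, `2` = 2L, `3` = 1L))

  s0 <- summarize_classification(ev2[0, ])
  expect_equal(s0$n_pulses, 0L)
  expect_true(is.na(s0$percent_polycyclic))
})
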