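# Shared fixtures, built in code at test time.

# A recording containing one multi-lobe pulse whose half-sine lobes have the
# given relative heights (alternating polarity), embedded in silence.
# Returns the recording plus the pulse window and nominal peak height.
lobe_recording <- function(heights, carrier_hz = 250, fs = 10000,
                           lead_s = 0.5, baseline = 0) {
  half <- as.integer(round(fs / (2 * carrier_hz)))
  lobe <- sin(pi * seq_len(half) / (half + 1))
  wave <- unlist(lapply(seq_along(heights), function(k) {
    heights[k] * lobe * (-1)^(k - 1)
  }))
  lead <- as.integer(lead_s * fs)
  x <- c(numeric(lead), wave, numeric(lead)) + baseline
  rec <- song_recording(x, fs, genotype = "constructed")
  list(
    recording = rec,
    window = list(window_start_s = (lead - 2) / fs,
                  window_end_s = (lead + length(wave) + 2) / fs),
    peak_height = max(heights)
  )
}

# Exhaustive two-sided Fisher p-value by hypergeometric enumeration over all
# tables with the observed margins (probabilities <= observed, standard
# convention with a small relative slack for float ties).
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b          # row-1 total
  n <- c + d          # row-2 total
  k <- a + c          # column-1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings.
mw_p_enum <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  mu <- nx * (n - nx) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Cached pipeline runs shared across acceptance blocks (built once).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

cro_snr10_run <- function() {
  cached("cro_snr10", function() {
    song <- generate_song(genotype_preset("cro"), 45, seed = 101)
    events <- analyze_pulses(song$recording)
    list(song = song, events = events,
         summary = summarize_classification(events))
  })
}

wildtype_long_run <- function() {
  cached("wildtype_long", function() {
    song <- generate_song(genotype_preset("wildtype"), 75, seed = 102)
    events <- analyze_pulses(song$recording)
    list(song = song, events = events)
  })
}
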