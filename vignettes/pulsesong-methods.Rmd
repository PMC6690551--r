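---
title: "Methods: quantifying Drosophila pulse song"
author: "pulsesong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Drosophila pulse song}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsesong)
```

## The measurement problem

Male *Drosophila melanogaster* court females with a wing-vibration song
whose *pulse song* component is a train of brief acoustic pulses separated
by an interpulse interval (IPI) of roughly 35 ms, with a carrier frequency
near 230 Hz; the *sine song* component is a sustained 120–180 Hz
oscillation. Mutations such as *croaker* (the Camta transcription-factor
locus) change the pulse shape — pulses become *polycyclic* (several
oscillation cycles of comparable amplitude instead of one dominant one) —
and prolong the IPI. Quantifying these phenotypes requires four
measurements from a single-channel microphone trace:

1. **Pulse detection and classification.** Each pulse's *peak height* is
   the distance between its largest positive-or-negative deflection and the
   *baseline*, defined as the mean voltage over the 3 s preceding the
   pulse's rising phase. The *slice level* is a fixed fraction of the peak
   height — 50% by default, 60% in a stringent variant for noisy
   recordings. Deflections other than the primary peak that exceed the
   slice level are *auxiliary peaks*; a pulse with none is monocyclic, with
   one or more is polycyclic. The cycle count is the number of counted
   peaks including the primary.
2. **IPI statistics.** IPIs are peak-to-peak intervals within bouts; their
   histogram is summarized by a fitted Gaussian.
3. **Carrier frequency.** Power spectra of pulses, averaged per pulse and
   optionally noise-subtracted, with the *maximal peak frequency* read off
   within a ~1–500 Hz band.
4. **Group comparisons.** Fisher's exact test on polycyclic incidence,
   one-way ANOVA with Bonferroni pairwise correction for IPI means,
   Mann–Whitney U for two-sample comparisons, and Kruskal–Wallis followed
   by Dwass–Steel–Critchlow–Fligner all-pairs or Steel many-to-one
   nonparametric comparisons for carrier frequencies and expression levels.

Because no public corpus of such recordings exists, the package ships a
synthetic generator that emulates wild-type-like and *cro*-like songs with
per-pulse ground truth, and the whole pipeline is validated against it.

## The spectrum grid

Spectra use 1024-point FFT segments at the nominal 10 kHz sampling rate,
i.e. a bin width of 9.765625 Hz. This grid is the single most consequential
numerical choice in the package: the carrier-frequency landmarks of the
phenotype — 234.4 Hz for wild-type-like pulses, 312.5 Hz for *cro*-like
monocyclic pulses, 351.6 Hz for *cro*-like polycyclic pulses — are exactly
bins 24, 32 and 36 of this grid, so peak frequencies reported by the
pipeline are directly comparable with published values at their printed
precision. Pulses shorter than the segment are mean-removed, Hann-tapered
over their own extent, centered and zero-padded; per-pulse periodograms are
averaged (Bartlett-style across events), with power normalized by
`N * sum(w^2)` so that the total over all bins equals the window-weighted
mean square of the segment (Parseval with window correction). Detected
windows are widened by 10 ms per side before the transform so the pulse's
sub-threshold ring-down is included; truncating it biases the spectral
peak low by about one bin.

## Filtering

The analysis band is ~1–500 Hz. The filter is a zero-phase (`filtfilt`)
cascade: order-2 Butterworth high-pass at the lower edge and order-4
Butterworth low-pass with its corner 20% above the upper edge. The corner
offset is deliberate: a Butterworth corner placed exactly at 500 Hz is 3 dB
down there and ~2 dB down at 450 Hz, whereas the song carriers must be
passed flat; with the 1.2× offset the band is flat within 1 dB up to
450 Hz while 2 kHz noise is attenuated by more than 40 dB. The mean is
subtracted before filtering, so DC is removed exactly. Detection,
classification and spectra all operate on this filtered trace; baselines
are therefore near zero by construction, and gain, DC-offset and
sign-inversion invariance of the classification are structural properties
(verified exactly in the tests).

## Detection without circularity

Defining detection by "events exceeding the slice level" is circular,
because the slice level is defined per pulse from the peak of the event
being detected. The package instead uses an absolute bootstrap threshold:
5 × the median absolute deviation (MAD) of the filtered trace. Pulses
occupy a tiny fraction of a recording, so the MAD estimates the noise
floor robustly, and the multiplier is unit-free. Two numerical guards are
applied: the threshold never falls below 1e-4 of the trace's maximal
absolute deflection (on noise-free synthetic traces the MAD would
otherwise be numerically zero), and events must persist for at least 1 ms
(an isolated suprathreshold noise sample is not a pulse). Above-threshold
samples separated by lulls of at most 5 ms form one event; events closer
than 10 ms merge (pulses are ~5–18 ms wide and IPIs at least ~15 ms, so
one pulse's lobes always merge and two pulses never do); events longer
than 50 ms are discarded as sustained oscillation, which is what rejects
sine song — a sustained 150 Hz segment either stays below 5 × MAD (it
dominates the MAD itself when long) or forms one over-long event.

## Cycle counting

Within each window the deflection from baseline is partitioned at its
zero-crossings; each same-sign lobe contributes its extremum as a
candidate peak, and additional same-lobe candidates are admitted only if
separated by at least 1 ms and by a dip below 50% of the smaller candidate.
This separation rule exists to keep noise ripple riding on a single lobe
from being counted as extra cycles — the same motivation that placed the
slice at 50% rather than 25%. Both polarities count, consistent with peak
height being measured to the largest positive *or* negative deflection;
equal maxima are broken toward the earlier sample.

## The synthetic pulse model

The generator's pulse is a carrier sinusoid under a piecewise envelope:
a flat plateau spanning the requested number of cycles, then a fast decay
to 20% of peak within one half-period, then a slow ring-down losing 35%
per half-period, truncated at 5% of peak. Cosine phase is used for odd
cycle counts (symmetric lobes), sine phase for even ones. The three
regimes serve three constraints that a single-parameter envelope (Hann or
single exponential) cannot satisfy simultaneously:

* the *n* plateau lobes exceed any slice level up to 60%, and the first
  off-plateau lobe stays well below the 50% slice even after band-pass
  filtering (the low-pass corner smears sharp envelopes upward by roughly
  0.1 of peak at a 350 Hz carrier);
* the slow ring-down concentrates spectral energy at the carrier, so the
  maximal peak frequency of even a one-cycle pulse falls on the grid bin
  nearest the carrier (short envelopes skew the periodogram peak below
  the carrier by up to one bin);
* total pulse width stays below ~18 ms, inside the 15 ms IPI floor.

These choices were fixed from the waveform geometry before the validation
suite was frozen, and the tests verify the resulting invariants: exact
cycle-count recovery for 1–4 cycles at 232/313/350 Hz carriers, raw and
filtered, at both slice levels, and spectral peaks on the documented bins.

The generator draws, in fixed order from a single stream seeded per call:
bout lengths (Poisson, mean 25 pulses, truncated at 2), IPIs (normal,
truncated at 15 ms), per-pulse class (Bernoulli at the polycyclic
fraction) and cycle count (the 65/34.5/0.5% mixture over 2/3/4 cycles),
then white noise. Presets: wild-type-like songs use a 232 Hz carrier,
35 ± 3 ms IPIs and no polycyclic pulses; *cro*-like songs use 313 Hz
(monocyclic) and 350 Hz (polycyclic) carriers, a 0.35 polycyclic fraction
and 40 ± 4 ms IPIs. The mutant IPI mean is a package choice — published
panels show prolongation without printing a value. The default noise SD
of 0.1 at unit pulse amplitude corresponds to a peak-amplitude
signal-to-noise ratio of 10, the regime the recovery guarantees are
stated for. Sine song is off by default and, when enabled, fills
inter-bout gaps with 20 ms on/off ramps; it exists to test detector
rejection, not to model sine-song biology.

What the generator does *not* emulate: microphone transfer functions,
amplitude variability within bouts, slow/fast pulse-mode switching, wing
attribution, or nonstationary noise. Passing the validation suite
therefore demonstrates correctness of the measurement procedure under the
stated signal model, not robustness to every artifact of real chambers.

## IPI analysis

IPIs are computed peak-to-peak within bouts; gaps above 100 ms split
bouts (the package's choice: ~3 × the wild-type IPI separates the 35 ms
mode from inter-bout silences by an order of magnitude). The Gaussian is
fitted to histogram counts (1 ms bins, resolving a 3 ms SD with ~12 bins
across ±2σ) by Levenberg–Marquardt least squares initialized at the
sample moments — mirroring the curve actually drawn over published
histograms — with direct moment-based MLE available as an alternative;
for genuinely Gaussian data the two agree within 2%. Fits require ≥30
intervals and ≥5 nonempty bins; zero-variance input is an error, and a
low R² (e.g. under 0.9 for a bimodal mixture) flags a poor fit rather
than failing.

## Statistics

The classical tests delegate to stock R (`fisher.test`, `wilcox.test`,
`aov`/`pairwise.t.test`, `kruskal.test`); the two multiple-comparison
procedures without a stock implementation are written here. The DSCF
all-pairs procedure re-ranks each pair alone, standardizes the rank sum
with tie correction, and refers `|z| * sqrt(2)` to the studentized range
with *k* means (`ptukey`). Steel's many-to-one procedure standardizes
each treatment-versus-control pair the same way and refers the family to
the maximum of correlated normals with the Steel correlation
`rho = sqrt(n_j n_k / ((n0+n_j)(n0+n_k)))` — exactly 0.5 at equal group
sizes — evaluated by seeded multivariate-normal quadrature so repeated
runs agree. Two-sided Fisher p-values follow the standard convention
(sum of hypergeometric probabilities no larger than the observed
table's); Mann–Whitney is exact by enumeration when the smaller sample
has ≤8 observations and no ties, and tie-corrected normal otherwise.
Significance stars follow the usual thresholds (0.05, 0.01, 0.001).

## Problem sizes in the validation suite

The test suite generates its songs at sizes chosen to give stable
statistics while keeping a full run comfortable on a laptop: 15–25 s
songs (~200–400 pulses) for deterministic round-trip and spectral-bin
checks, a 45 s *cro*-preset song (~700 pulses, ≥200 polycyclic) for
incidence and cycle-composition recovery, a 75 s wild-type song (~1300
IPIs) for the end-to-end Gaussian fit, 2000 null simulations per test for
type-I error calibration, and the complete enumeration of all 2×2 tables
with total ≤20 for Fisher's test. The acceptance script regenerates all
of these from scratch at the seed it is given, using a 120 s *cro*-preset
song (~1900 pulses, ~650 polycyclic) for incidence and composition so the
binomial sampling error of the cycle-composition percentage stays near
two points regardless of the seed.

## Known limitations

* The WAV reader supports mono 16-bit PCM and 32-bit float only; other
  encodings and the proprietary acquisition formats of physiology
  hardware are out of scope.
* Classification accuracy is characterized at SNR ≥ 10; noisier
  recordings should use the 60% slice variant, which trades sensitivity
  to genuine auxiliary peaks for robustness (as in the published
  stringent reanalysis).
* The detector's 50 ms maximum event duration means genuinely overlapping
  pulse trains (IPI < ~10 ms) would merge; such songs do not occur in
  the modeled genotypes.
* Histogram-based Gaussian fitting inherits binning sensitivity for very
  small samples; below ~100 intervals the MLE option is more stable.
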