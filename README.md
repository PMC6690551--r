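# pulsesong

Quantification of *Drosophila* male courtship **pulse song** from
single-channel acoustic recordings: pulse detection, monocyclic/polycyclic
classification by the slice-level criterion, interpulse-interval (IPI)
statistics with Gaussian fitting, per-pulse power spectra with noise
subtraction and carrier-frequency estimation, and the group-comparison
statistics used in song phenotyping. It is written for neuroethologists and
behavioral geneticists who score song phenotypes — for example the
polycyclic pulses and prolonged IPIs of *croaker*/Camta mutants — and who
need the scoring to be reproducible, scriptable and testable.

## The measurements

For each detected pulse, the **baseline** is the mean voltage of the 3 s
preceding its rising phase, and the **peak height** *h* is the distance
from the baseline to the largest positive-or-negative deflection. With a
slice fraction *s* (0.5 by default, 0.6 in the stringent variant), the
**slice level** is *s·h*; every deflection other than the primary peak
exceeding the slice level is an auxiliary peak. A pulse with cycle count
*c* = 1 (no auxiliary peaks) is **monocyclic**, with *c* ≥ 2
**polycyclic**. Within bouts (gaps ≤ 100 ms), the IPI sequence is
summarized by a least-squares Gaussian *a·exp(−(x−μ)²/2σ²)* fitted to its
1 ms histogram. Carrier frequencies are maximal peaks of averaged,
optionally noise-subtracted periodograms on a 1024-point grid at 10 kHz
(bin width 9.765625 Hz) inside a ~1–500 Hz band. Group comparisons:
Fisher's exact test (polycyclic incidence), Mann–Whitney U, one-way ANOVA
with Bonferroni pairwise correction (IPI means), Kruskal–Wallis with
Dwass–Steel–Critchlow–Fligner all-pairs or Steel many-to-one comparisons
(carrier frequencies, expression levels).

A synthetic song generator (`genotype_preset()`, `generate_song()`)
produces wild-type-like and *cro*-like recordings with per-pulse ground
truth, so every stage of the pipeline is validated without any external
data. See the methods vignette (`vignettes/pulsesong-methods.Rmd`) for the
models and numerical choices.

## Worked example

```r
library(pulsesong)

song <- generate_song(genotype_preset("cro"), duration_s = 40, seed = 2)
res  <- analyze_song(song$recording)
res
#> <song_results> cro: 631 pulses, 31.1% polycyclic; IPI mu = 39.8 ms; peak 312.5 Hz

res$summary$peak_hz
#> $all
#> [1] 312.5
#> $monocyclic
#> [1] 312.5
#> $polycyclic
#> [1] 351.5625

res$summary$gaussian_fit[c("mu_ms", "sigma_ms", "r_squared")]
#> $mu_ms
#> [1] 39.81726
#> $sigma_ms
#> [1] 4.423108
#> $r_squared
#> [1] 0.9622632
```

Of the 631 detected pulses, 31.1% are polycyclic (the *cro* hallmark; the
control preset stays below 2%), the monocyclic carrier sits on the
312.5 Hz bin and the polycyclic carrier on the 351.6 Hz bin, and the
fitted IPI mean of ~40 ms reflects the mutant's prolonged interval
(wild-type-like songs fit ~35 ms). `write_results()` saves the pulse, IPI
and spectrum tables as CSV plus a JSON summary; `compare_summaries()`
tests polycyclic incidence between genotypes.

A command-line interface covers the same workflow
(`inst/scripts/pulsesong`):

```sh
pulsesong generate --preset cro --seed 2 --duration 40 --out cro_song
pulsesong analyze cro_song/song.wav --slice 0.5 --out cro_song/res
pulsesong compare wt/res/summary.json cro_song/res/summary.json
```

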