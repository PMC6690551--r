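Package: pulsesong
Title: Quantification of Drosophila Courtship Pulse Song
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detection and classification of courtship song pulses from
    single-channel acoustic recordings of Drosophila males. Implements the
    slice-level criterion for monocyclic versus polycyclic pulse
    classification, interpulse-interval extraction with Gaussian fitting,
    per-pulse power spectra with noise subtraction and carrier-frequency
    estimation, and the parametric and nonparametric group-comparison
    statistics used in song phenotyping (Fisher's exact test, Mann-Whitney U,
    one-way ANOVA with Bonferroni correction, Kruskal-Wallis with
    Dwass-Steel-Critchlow-Fligner all-pairs and Steel many-to-one
    comparisons). Includes a synthetic song generator with per-pulse ground
    truth for validating every pipeline stage, and WAV/CSV/JSON input-output
    with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    mvtnorm,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
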