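#' Run the full song-analysis pipeline on a recording
#'
#' Band-passes the trace, detects and classifies pulses by the slice-level
#' criterion, computes within-bout interpulse intervals and their Gaussian
#' fit, and estimates averaged power spectra: one over all pulses (raw), one
#' of song-free noise, and noise-subtracted spectra stratified by pulse
#' class.
#'
#' @param recording A [song_recording()].
#' @param config An [analysis_config()].
#' @return An object of class `song_results` with `pulse_table`,
#'   `ipi_table`, `spectrum_table` (long tibble: class, freq_hz, power,
#'   noise_subtracted) and `summary` (per-genotype aggregates: pulse counts,
#'   percent polycyclic, cycle histogram, Gaussian-fit parameters, peak
#'   frequencies per class).
#' @export
analyze_song <- function(recording, config = analysis_config()) {
  stopifnot(inherits(recording, "song_recording"))
  filtered <- bandpass_filter(recording, config$band_low_hz,
                              config$band_high_hz)
  events <- analyze_pulses(recording, config)
  cls <- summarize_classification(events)
  ipis <- compute_ipis(events, config$bout_break_ms)

  fit <- NULL
  if (nrow(ipis) >= 30L && stats::sd(ipis$ipi_ms) > 0) {
    fit <- tryCatch(fit_gaussian(ipis, config$ipi_bin_width_ms),
                    error = function(e) NULL)
  }

  spec_rows <- list()
  peaks <- list()
  if (nrow(events) > 0L) {
    all_spec <- pulse_spectrum(filtered, events, config)
    spec_rows[["all"]] <- spectrum_rows("all", all_spec)
    peaks[["all"]] <- all_spec$peak_hz
    strat <- tryCatch(
      withCallingHandlers(
        stratified_spectra(filtered, events, config),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) list()
    )
    for (cls_name in names(strat)) {
      spec_rows[[cls_name]] <- spectrum_rows(cls_name, strat[[cls_name]])
      peaks[[cls_name]] <- strat[[cls_name]]$peak_hz
    }
  }
  spectrum_table <- if (length(spec_rows) > 0L) {
    do.call(rbind, spec_rows)
  } else {
    tibble::tibble(class = character(), freq_hz = numeric(),
                   power = numeric(), noise_subtracted = logical())
  }

  pulse_table <- events
  pulse_table$peak_times <- NULL

  summary <- list(
    genotype = recording$genotype,
    source = recording$source,
    n_pulses = cls$n_pulses,
    n_polycyclic = cls$n_polycyclic,
    percent_polycyclic = cls$percent_polycyclic,
    cycle_histogram = as.list(cls$cycle_histogram),
    n_ipis = nrow(ipis),
    gaussian_fit = if (!is.null(fit)) {
      list(mu_ms = fit$mu_ms, sigma_ms = fit$sigma_ms,
           amplitude = fit$amplitude, r_squared = fit$r_squared,
           n = fit$n, bin_width_ms = fit$bin_width_ms)
    } else NULL,
    peak_hz = peaks,
    slice_fraction = config$slice_fraction
  )

  structure(
    list(pulse_table = pulse_table, ipi_table = ipis,
         spectrum_table = spectrum_table, summary = summary),
    class = "song_results"
  )
}

spectrum_rows <- function(cls, spec) {
  tibble::tibble(class = cls, freq_hz = spec$freq_hz, power = spec$power,
                 noise_subtracted = spec$noise_subtracted)
}

#' @export
print.song_results <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<song_results> %s: %d pulses", s$genotype, s$n_pulses))
  if (!is.na(s$percent_polycyclic)) {
    cat(sprintf(", %.1f%% polycyclic", s$percent_polycyclic))
  }
  if (!is.null(s$gaussian_fit)) {
    cat(sprintf("; IPI mu = %.1f ms", s$gaussian_fit$mu_ms))
  }
  if (!is.null(s$peak_hz$all)) {
    cat(sprintf("; peak %.1f Hz", s$peak_hz$all))
  }
  cat("\n")
  invisible(x)
}

#' Write analysis results to a directory
#'
#' Writes `pulse_table.csv`, `ipi_table.csv` and `spectrum_table.csv`
#' (RFC-4180, fixed column order) plus `summary.json`. The files round-trip
#' through [read_results()] into an equal bundle.
#'
#' @param bundle A `song_results` object from [analyze_song()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "song_results"))
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  paths <- c(
    pulse = file.path(out_dir, "pulse_table.csv"),
    ipi = file.path(out_dir, "ipi_table.csv"),
    spectrum = file.path(out_dir, "spectrum_table.csv"),
    summary = file.path(out_dir, "summary.json")
  )
  utils::write.csv(bundle$pulse_table, paths["pulse"], row.names = FALSE)
  utils::write.csv(bundle$ipi_table, paths["ipi"], row.names = FALSE)
  utils::write.csv(bundle$spectrum_table, paths["spectrum"],
                   row.names = FALSE)
  jsonlite::write_json(bundle$summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(unname(paths))
}

#' Read analysis results back from a directory
#'
#' @param out_dir Directory previously written by [write_results()].
#' @return A `song_results` bundle.
#' @export
read_results <- function(out_dir) {
  pulse <- tibble::as_tibble(utils::read.csv(
    file.path(out_dir, "pulse_table.csv"),
    colClasses = c(class = "character")
  ))
  ipi <- tibble::as_tibble(utils::read.csv(file.path(out_dir,
                                                     "ipi_table.csv")))
  spectrum <- tibble::as_tibble(utils::read.csv(
    file.path(out_dir, "spectrum_table.csv"),
    colClasses = c(class = "character")
  ))
  summary <- jsonlite::read_json(file.path(out_dir, "summary.json"),
                                 simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (length(summary$peak_hz) == 0L) summary$peak_hz <- list()
  structure(
    list(pulse_table = pulse, ipi_table = ipi, spectrum_table = spectrum,
         summary = summary),
    class = "song_results"
  )
}

#' Compare polycyclic incidence between summaries
#'
#' Builds the 2x2 monocyclic/polycyclic contingency table for each pair of
#' summaries and applies Fisher's exact test, comparing every other summary
#' against the first.
#'
#' @param summaries List of >= 2 summary lists (the `summary` element of
#'   [analyze_song()] results, or as re-read from `summary.json`).
#' @return Tibble with one row per comparison: labels, counts, odds ratio
#'   and p-value with significance stars.
#' @export
compare_summaries <- function(summaries) {
  if (length(summaries) < 2L) stop("need at least two summaries",
                                   call. = FALSE)
  ref <- summaries[[1]]
  rows <- lapply(summaries[-1], function(s) {
    tab <- matrix(c(ref$n_pulses - ref$n_polycyclic, ref$n_polycyclic,
                    s$n_pulses - s$n_polycyclic, s$n_polycyclic),
                  2L, 2L, byrow = TRUE)
    rep <- fisher_exact(tab)
    tibble::tibble(
      reference = ref$genotype %||% "group1",
      comparison = s$genotype %||% "group2",
      ref_poly_pct = ref$percent_polycyclic,
      cmp_poly_pct = s$percent_polycyclic,
      odds_ratio = rep$statistic,
      p_value = rep$p_value,
      stars = significance_stars(rep$p_value)
    )
  })
  do.call(rbind, rows)
}
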