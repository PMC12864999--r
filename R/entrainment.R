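#' Entrainment success criterion
#'
#' Assesses whether pre-stimulus stimulation succeeded for one participant:
#' the percent-change power time course, averaged over the occipital
#' electrodes (O1, O2, Oz) and the stimulation band (stimulation frequency
#' +- 1 Hz), must reach at least `threshold` percent for a contiguous span of
#' at least `min_duration_ms` within the late entrainment window (-1.1 to
#' -0.1 s relative to stimulus onset; entrainment develops over time, so the
#' late half of the stimulation interval is assessed). With the 100 ms TFR
#' step, "at least 500 ms" means at least 5 contiguous time bins at or above
#' threshold.
#'
#' @param tfr a percent-change `tfr_volume` for one participant.
#' @param stim_freq stimulation frequency in Hz (5 or 9).
#' @param threshold percent-change threshold (default 10).
#' @param min_duration_ms minimum contiguous supra-threshold duration
#'   (default 500).
#' @param window assessment window in seconds (default `c(-1.1, -0.1)`).
#' @param channels occipital electrode set (default O1, O2, Oz).
#' @return object of class `entrainment_assessment`: list with `timecourse`,
#'   `times`, `band`, `max_percent_change` (entrainment strength),
#'   `sustained_ms` (longest supra-threshold run) and `passed`.
#' @export
assess_entrainment <- function(tfr, stim_freq, threshold = 10,
                               min_duration_ms = 500,
                               window = c(-1.1, -0.1),
                               channels = c("O1", "O2", "Oz")) {
  stopifnot(inherits(tfr, "tfr_volume"))
  if (tfr$baseline_mode != "percent_change")
    stop("assess_entrainment expects a percent-change baselined TFR")
  ci <- match(channels, tfr$channel_labels)
  if (anyNA(ci))
    stop("missing occipital channel(s): ",
         paste(channels[is.na(ci)], collapse = ", "))
  band <- (stim_freq - 1):(stim_freq + 1)
  fi <- match(band, tfr$freqs)
  if (anyNA(fi)) stop("stimulation band outside the frequency axis")
  ti <- which(tfr$times >= window[1] - 1e-9 & tfr$times <= window[2] + 1e-9)
  step_ms <- round(1000 * stats::median(diff(tfr$times)), 6)
  tc <- apply(tfr$power[ci, fi, ti, drop = FALSE], 3, mean)
  above <- tc >= threshold
  runs <- rle(above)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  # a run of m bins counts as m x step; the window span (1000 ms) caps it
  sustained_ms <- min(longest * step_ms, 1000 * (window[2] - window[1]))
  structure(list(
    timecourse = tc, times = tfr$times[ti], band = band, window = window,
    channels = channels, threshold = threshold,
    max_percent_change = max(tc), sustained_ms = sustained_ms,
    passed = sustained_ms >= min_duration_ms
  ), class = "entrainment_assessment")
}

#' @export
print.entrainment_assessment <- function(x, ...) {
  cat(sprintf("Entrainment %s: max %.1f%% change, sustained %d ms >= %g%% in (%g, %g) s\n",
              if (x$passed) "PASSED" else "failed", x$max_percent_change,
              round(x$sustained_ms), x$threshold, x$window[1], x$window[2]))
  invisible(x)
}

#' Default posterior electrode set for spectral peak extraction
#' @return character vector of 9 posterior 10-20 labels.
#' @export
posterior_electrodes <- function() {
  c("Pz", "POz", "Oz", "O1", "O2", "P3", "P4", "PO3", "PO4")
}

#' Individual spectral peak (IAF / ITF) extraction
#'
#' Finds the frequency with maximum resting-state power within a band
#' (alpha 8-12 Hz for the individual alpha frequency, theta 3-7 Hz for the
#' individual theta frequency), averaged over a posterior electrode set.
#' Ties are broken toward the lower frequency with a warning.
#'
#' @param spectrum a `power_spectrum`.
#' @param band numeric length-2 frequency range in Hz.
#' @param electrodes electrode labels to average (default the nine-electrode
#'   posterior set).
#' @return object of class `spectral_peak`: list with `peak_frequency_hz`,
#'   `band`, `electrodes`, `band_power`.
#' @export
extract_band_peak <- function(spectrum, band = c(8, 12),
                              electrodes = posterior_electrodes()) {
  stopifnot(inherits(spectrum, "power_spectrum"), length(band) == 2)
  ci <- match(electrodes, spectrum$channel_labels)
  if (anyNA(ci))
    stop("missing electrode(s): ",
         paste(electrodes[is.na(ci)], collapse = ", "))
  fi <- which(spectrum$freqs >= band[1] & spectrum$freqs <= band[2])
  if (length(fi) == 0) stop("band outside the frequency grid")
  p <- colMeans(spectrum$power[ci, fi, drop = FALSE])
  mx <- max(p)
  at <- which(p >= mx - 1e-12 * abs(mx))
  if (length(at) > 1)
    warning("tied band maximum; returning the lowest frequency")
  structure(list(peak_frequency_hz = spectrum$freqs[fi][min(at)],
                 band = band, electrodes = electrodes, band_power = p),
            class = "spectral_peak")
}

#' Frequency distance between an individual peak and the stimulation frequency
#' @param peak a `spectral_peak` (or a numeric peak frequency).
#' @param stim_freq stimulation frequency in Hz.
#' @return absolute distance in Hz.
#' @export
peak_distance <- function(peak, stim_freq) {
  f <- if (inherits(peak, "spectral_peak")) peak$peak_frequency_hz else peak
  abs(f - stim_freq)
}

#' Correlation between frequency distance and entrainment strength
#'
#' Pearson product-moment correlation (with t-based two-sided p) between the
#' per-participant distance of the individual peak frequency from the
#' stimulation frequency and the per-participant maximal relative power change
#' (entrainment strength).
#'
#' @param distances per-participant |peak - stimulation| in Hz.
#' @param strengths per-participant maximal percent change.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
distance_strength_correlation <- function(distances, strengths) {
  stopifnot(length(distances) == length(strengths))
  if (length(distances) < 3) stop("need at least 3 participants")
  if (!all(is.finite(distances)) || !all(is.finite(strengths)))
    stop("non-finite values")
  if (var(distances) == 0 || var(strengths) == 0)
    stop("zero variance in distances or strengths")
  ct <- cor.test(distances, strengths, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(distances))
}

#' Tabulate entrainment assessments across participants
#'
#' @param assessments named list of `entrainment_assessment` objects.
#' @param groups optional character vector of group ids, same length.
#' @return data.frame (`participant`, `group`, `passed`, `max_change`,
#'   `sustained_ms`).
#' @export
entrainment_table <- function(assessments, groups = NA_character_) {
  data.frame(
    participant = if (is.null(names(assessments)))
      seq_along(assessments) else names(assessments),
    group = groups,
    passed = vapply(assessments, `[[`, logical(1), "passed"),
    max_change = vapply(assessments, `[[`, numeric(1), "max_percent_change"),
    sustained_ms = vapply(assessments, `[[`, numeric(1), "sustained_ms"),
    row.names = NULL)
}
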