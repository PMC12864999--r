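#' Luminance modulation waveforms for pre-stimulus visual entrainment
#'
#' The entrainment stimulus is an image whose luminance is modulated over a 2 s
#' pre-stimulus interval. In the rhythmic conditions the luminance follows a
#' raised cosine at the stimulation frequency, \eqn{L(t) = (1 - \cos(2\pi f
#' t))/2}, so the image starts and ends invisible (luminance 0) and reaches
#' full luminance at every half cycle. The arhythmic control chains complete
#' single raised-cosine cycles whose frequencies are drawn at random from an
#' integer pool spanning 13-24 Hz with the harmonics of the rhythmic
#' frequencies (15, 18, 20 Hz) excluded.
#'
#' Waveforms are sampled on the closed frame grid `t = k / frame_rate`,
#' `k = 0..n` with `n = duration_s * frame_rate`: the only uniform grid with
#' exact frame spacing on which both the first and the last frame are exactly
#' zero for an integer number of cycles.
#'
#' @param frequency_hz stimulation frequency in Hz (5 for the theta group,
#'   9 for the alpha group).
#' @param duration_s stimulation duration in seconds; `duration_s *
#'   frequency_hz` must be an integer number of cycles.
#' @param frame_rate display frame rate in frames per second (default 240,
#'   giving a frame interval of ~4.2 ms).
#' @return an object of class `luminance_waveform`: a list with
#'   `frame_values` (luminance fractions in `[0, 1]`), `times_s`, `frame_rate`,
#'   `kind` (`"rhythmic"` or `"arhythmic"`), `frequency_hz` (rhythmic),
#'   `cycle_frequencies_hz` (arhythmic), `duration_s` and `gap_ms`.
#' @examples
#' wf <- make_rhythmic_waveform(5, 2)
#' range(wf$frame_values)
#' @export
make_rhythmic_waveform <- function(frequency_hz, duration_s, frame_rate = 240) {
  stopifnot(is.numeric(frequency_hz), length(frequency_hz) == 1L,
            is.numeric(duration_s), length(duration_s) == 1L)
  if (frequency_hz <= 0) stop("frequency_hz must be > 0")
  if (frame_rate < 2 * frequency_hz)
    stop("frame_rate must be at least twice the stimulation frequency")
  n_cycles <- duration_s * frequency_hz
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop(sprintf("duration_s * frequency_hz = %.6f is not an integer number of cycles",
                 n_cycles))
  n <- round(duration_s * frame_rate)
  t <- (0:n) / frame_rate
  lum <- (1 - cos(2 * pi * frequency_hz * t)) / 2
  # exact zeros at the cycle boundaries (guard rounding in cos)
  lum[1] <- 0
  lum[n + 1L] <- 0
  structure(list(
    frame_values = lum,
    times_s = t,
    frame_rate = frame_rate,
    kind = "rhythmic",
    frequency_hz = frequency_hz,
    cycle_frequencies_hz = NULL,
    duration_s = duration_s,
    gap_ms = post_stimulation_gap(frequency_hz)
  ), class = "luminance_waveform")
}

#' Integer frequency pool for the arhythmic control waveform
#'
#' 13-24 Hz excluding 15, 18 and 20 Hz, the harmonics of the 5 Hz and 9 Hz
#' stimulation frequencies.
#'
#' @return integer vector of allowed cycle frequencies in Hz.
#' @export
arhythmic_frequency_pool <- function() {
  c(13L, 14L, 16L, 17L, 19L, 21L, 22L, 23L, 24L)
}

#' @rdname make_rhythmic_waveform
#' @param target_duration_s target total duration in seconds (default 2);
#'   single cycles are appended while the running total does not exceed it
#'   (greedy stop-before-overflow), so the realized duration is at most
#'   `target_duration_s` and falls short by less than one maximal cycle.
#' @param frequency_pool allowed integer cycle frequencies in Hz; must not
#'   contain 15, 18 or 20.
#' @param seed optional integer seed; with the same seed the waveform is
#'   bit-identical across calls.
#' @export
make_arhythmic_waveform <- function(target_duration_s = 2,
                                    frequency_pool = arhythmic_frequency_pool(),
                                    seed = NULL, frame_rate = 240) {
  if (any(frequency_pool %in% c(15, 18, 20)))
    stop("frequency_pool must not contain 15, 18 or 20 Hz (harmonics of 5 and 9 Hz)")
  if (any(frequency_pool <= 0)) stop("cycle frequencies must be > 0")
  if (!is.null(seed)) set.seed(seed)
  cycles <- draw_arhythmic_cycles(target_duration_s, frequency_pool)
  duration <- sum(1 / cycles)
  # evaluate the piecewise raised-cosine chain on the frame grid; the exact
  # chain endpoint (where luminance returns to 0) is appended as final frame
  t <- seq(0, duration, by = 1 / frame_rate)
  if (t[length(t)] < duration) t <- c(t, duration)
  onsets <- cumsum(c(0, 1 / cycles))
  idx <- findInterval(t, onsets, rightmost.closed = TRUE)
  idx[idx > length(cycles)] <- length(cycles)
  lum <- (1 - cos(2 * pi * cycles[idx] * (t - onsets[idx]))) / 2
  lum[1] <- 0
  lum[length(lum)] <- 0
  structure(list(
    frame_values = lum,
    times_s = t,
    frame_rate = frame_rate,
    kind = "arhythmic",
    frequency_hz = NULL,
    cycle_frequencies_hz = cycles,
    duration_s = duration,
    gap_ms = post_stimulation_gap(arhythmic = TRUE)
  ), class = "luminance_waveform")
}

# draw the cycle frequency sequence: append complete cycles while the total
# duration stays within the target (greedy stop-before-overflow)
draw_arhythmic_cycles <- function(target_duration_s, frequency_pool) {
  cycles <- numeric(0)
  total <- 0
  repeat {
    f <- frequency_pool[sample.int(length(frequency_pool), 1L)]
    if (total + 1 / f > target_duration_s) break
    cycles <- c(cycles, f)
    total <- total + 1 / f
  }
  cycles
}

#' Dark gap between stimulation offset and stimulus onset
#'
#' The stimulus pair is presented in phase with the entrainment rhythm: a dark
#' gap of half a stimulation cycle separates the end of the luminance waveform
#' from stimulus onset (100 ms at 5 Hz, 56 ms at 9 Hz). The arhythmic control
#' uses a fixed 50 ms gap.
#'
#' @param frequency_hz stimulation frequency in Hz (ignored when
#'   `arhythmic = TRUE`).
#' @param arhythmic logical; arhythmic control condition.
#' @return gap duration in integer milliseconds.
#' @export
post_stimulation_gap <- function(frequency_hz = NULL, arhythmic = FALSE) {
  if (isTRUE(arhythmic)) return(50)
  if (is.null(frequency_hz) || !is.numeric(frequency_hz) || frequency_hz <= 0)
    stop("frequency_hz must be > 0 (or set arhythmic = TRUE)")
  round(1000 / (2 * frequency_hz))
}

#' @export
print.luminance_waveform <- function(x, ...) {
  if (x$kind == "rhythmic") {
    cat(sprintf("Rhythmic luminance waveform: %g Hz, %.3f s, %d fps, gap %d ms\n",
                x$frequency_hz, x$duration_s, x$frame_rate, x$gap_ms))
  } else {
    cat(sprintf("Arhythmic luminance waveform: %d cycles (%s Hz), %.3f s, gap %d ms\n",
                length(x$cycle_frequencies_hz),
                paste(range(x$cycle_frequencies_hz), collapse = "-"),
                x$duration_s, x$gap_ms))
  }
  invisible(x)
}

#' Export a waveform as TSV plus JSON metadata
#'
#' Writes a two-column TSV (`time_s`, `luminance`) and, alongside it, a
#' `.json` file with the waveform metadata (kind, frequency or cycle
#' frequencies, duration, frame rate, gap).
#'
#' @param waveform a `luminance_waveform`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_tsv <- function(waveform, path) {
  stopifnot(inherits(waveform, "luminance_waveform"))
  write.table(data.frame(time_s = waveform$times_s,
                         luminance = waveform$frame_values),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- waveform[c("kind", "frequency_hz", "cycle_frequencies_hz",
                     "duration_s", "frame_rate", "gap_ms")]
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
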