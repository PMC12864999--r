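#' Construct an epoch set
#'
#' The central EEG container: a trials x channels x samples array with its
#' time axis, channel labels, per-trial metadata and a rejection log.
#'
#' @param data numeric array, trials x channels x samples.
#' @param sampling_rate Hz.
#' @param t_start time (s) of the first sample relative to stimulus onset.
#' @param channel_labels character vector, one per channel.
#' @param metadata data.frame with one row per trial.
#' @return object of class `epoch_set`.
#' @export
new_epoch_set <- function(data, sampling_rate, t_start, channel_labels,
                          metadata = NULL) {
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == length(channel_labels))
  n <- dim(data)[3]
  times <- t_start + (seq_len(n) - 1) / sampling_rate
  if (is.null(metadata))
    metadata <- data.frame(trial = seq_len(dim(data)[1]))
  structure(list(
    data = data, sampling_rate = sampling_rate, times_s = times,
    t_start = t_start, t_end = t_start + n / sampling_rate,
    channel_labels = channel_labels, metadata = metadata,
    rejected = data.frame(trial = integer(0), reason = character(0),
                          score = numeric(0))
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples (%.1f..%.1f s @ %g Hz), %d rejected\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$times_s[1], x$times_s[length(x$times_s)], x$sampling_rate,
              nrow(x$rejected)))
  invisible(x)
}

#' Number of trials/channels in an epoch set
#' @param epochs an `epoch_set`.
#' @return integer count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Indices of trials not flagged by artifact rejection
#' @param epochs an `epoch_set`.
#' @return integer vector of retained trial indices.
#' @export
clean_trials <- function(epochs) {
  setdiff(seq_len(n_trials(epochs)), epochs$rejected$trial)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, applied per channel.
#' The study band is 0.5-40 Hz. Accepts a continuous recording, a channels x
#' samples matrix, or an `epoch_set` (filtered per trial).
#'
#' @param x `eeg_recording`, `epoch_set`, or channels x samples matrix.
#' @param low,high band edges in Hz; `0 < low < high < ` Nyquist.
#' @param sampling_rate required for a bare matrix.
#' @param order Butterworth order of the underlying one-pass filter.
#' @return the filtered object, same class as the input.
#' @export
bandpass <- function(x, low = 0.5, high = 40, sampling_rate = NULL, order = 4) {
  UseMethod("bandpass")
}

#' @export
bandpass.eeg_recording <- function(x, low = 0.5, high = 40,
                                   sampling_rate = NULL, order = 4) {
  x$data <- bandpass.default(x$data, low, high, x$sampling_rate, order)
  x
}

#' @export
bandpass.epoch_set <- function(x, low = 0.5, high = 40, sampling_rate = NULL,
                               order = 4) {
  for (i in seq_len(n_trials(x)))
    x$data[i, , ] <- bandpass.default(x$data[i, , , drop = TRUE], low, high,
                                      x$sampling_rate, order)
  x
}

#' @export
bandpass.default <- function(x, low = 0.5, high = 40, sampling_rate = NULL,
                             order = 4) {
  if (is.null(sampling_rate)) stop("sampling_rate required for matrix input")
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band (%g, %g) must satisfy 0 < low < high < Nyquist (%g)",
                 low, high, nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
    attributes(out) <- attributes(x)
    out
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Epoch a continuous recording around stimulus-onset markers
#'
#' Cuts one epoch per event marker, spanning `t_start` to `t_end` seconds
#' relative to the marker. Sample 1 of the epoch time axis maps to `t_start`;
#' the onset falls at sample index `-t_start * sampling_rate + 1`. Markers too
#' close to the recording edge yield a zero-filled epoch flagged with reason
#' `"edge"` rather than being silently dropped.
#'
#' @param recording an `eeg_recording`.
#' @param events integer sample indices of stimulus onsets (defaults to the
#'   recording's own event table).
#' @param t_start,t_end epoch window in seconds relative to onset (defaults
#'   -3.4 and 2.5, the study's encoding epoch).
#' @return an `epoch_set`.
#' @export
epoch_recording <- function(recording, events = recording$events$sample,
                            t_start = -3.4, t_end = 2.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  n <- round((t_end - t_start) * fs)
  nch <- nrow(recording$data)
  nev <- length(events)
  dat <- array(0, c(nev, nch, n))
  flagged <- logical(nev)
  total <- ncol(recording$data)
  for (i in seq_len(nev)) {
    first <- events[i] + round(t_start * fs)
    last <- first + n - 1L
    if (first < 1L || last > total) {
      flagged[i] <- TRUE
    } else {
      dat[i, , ] <- recording$data[, first:last]
    }
  }
  es <- new_epoch_set(dat, fs, t_start, recording$channel_labels,
                      metadata = data.frame(trial = seq_len(nev),
                                            onset_sample = events))
  if (any(flagged))
    es$rejected <- data.frame(trial = which(flagged), reason = "edge",
                              score = NA_real_)
  es
}

# FFT-based analytic-signal envelope, optionally band-limited; x may be a
# samples x channels matrix (envelope per column)
hilbert_envelope <- function(x, band = NULL, sampling_rate = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  if (!is.null(band)) {
    f <- (seq_len(n) - 1) * sampling_rate / n
    h[f < band[1] | f > band[2]] <- 0
  }
  Mod(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n)
}

#' Automated z-score artifact rejection
#'
#' Replicates the accumulated z-value approach: per artifact type a
#' type-specific feature time series is computed per channel and trial
#' (jump: absolute first difference of the median-subtracted signal;
#' muscle: 30-40 Hz band-limited Hilbert envelope, the high-frequency
#' surrogate available inside 0.5-40 Hz data), z-transformed per channel
#' against the mean and SD pooled over the whole epoch set, accumulated
#' across channels (sum divided by the square root of the channel count, the
#' accumulated-z convention under which the printed cutoffs are calibrated),
#' and reduced to a per-trial maximum over time (the accumulated
#' z-score). Trials whose score exceeds the type's cutoff (defaults z = 60
#' for jumps, z = 30 for muscle) are flagged with that reason; a trial
#' exceeding both cutoffs is flagged as jump.
#'
#' @param epochs an `epoch_set` with at least 2 trials.
#' @param jump_threshold,muscle_threshold accumulated z cutoffs.
#' @param channels channels entering detection (default: all non-EOG).
#' @return the `epoch_set` with its `rejected` log extended; per-trial scores
#'   are attached as attribute `artifact_scores`.
#' @export
zscore_artifact_reject <- function(epochs, jump_threshold = 60,
                                   muscle_threshold = 30, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"),
            jump_threshold > 0, muscle_threshold > 0)
  nt <- n_trials(epochs)
  if (nt < 2) stop("z-transform undefined with fewer than 2 trials")
  if (is.null(channels))
    channels <- epochs$channel_labels[!grepl("EOG", epochs$channel_labels)]
  ci <- match(channels, epochs$channel_labels)
  fs <- epochs$sampling_rate

  feature_scores <- function(feat_fun) {
    # feat: per trial, channels x samples -> channels x samples feature;
    # z per channel over the whole epoch set, summed over channels and
    # scaled by 1/sqrt(nchan); per-trial max over time = accumulated z
    n <- dim(epochs$data)[3]
    feats <- array(0, c(nt, length(ci), n))
    for (i in seq_len(nt))
      feats[i, , ] <- feat_fun(epochs$data[i, ci, , drop = TRUE])
    for (j in seq_along(ci)) {
      v <- feats[, j, ]
      feats[, j, ] <- (v - mean(v)) / sd(as.vector(v))
    }
    zacc <- colMeans(aperm(feats, c(2, 1, 3))) * sqrt(length(ci))
    apply(zacc, 1, max)
  }

  jump_score <- feature_scores(function(x) {
    d <- abs(t(diff(t(x - apply(x, 1, median)))))
    cbind(d, d[, ncol(d)])
  })
  muscle_score <- feature_scores(function(x)
    t(hilbert_envelope(t(x), band = c(30, 40), sampling_rate = fs)))

  flag_jump <- jump_score > jump_threshold
  flag_muscle <- muscle_score > muscle_threshold & !flag_jump
  new_flags <- rbind(
    data.frame(trial = which(flag_jump),
               reason = rep("jump", sum(flag_jump)),
               score = jump_score[flag_jump]),
    data.frame(trial = which(flag_muscle),
               reason = rep("muscle", sum(flag_muscle)),
               score = muscle_score[flag_muscle]))
  keep <- !(epochs$rejected$trial %in% new_flags$trial)
  epochs$rejected <- rbind(epochs$rejected[keep, ], new_flags)
  attr(epochs, "artifact_scores") <- data.frame(
    trial = seq_len(nt), jump = jump_score, muscle = muscle_score)
  epochs
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every sample of every trial, the mean across the included
#' scalp channels. EOG (or otherwise excluded) channels are left untouched.
#' The operation is idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param exclude channel labels excluded from (and untouched by) the
#'   reference (default: channels whose label contains "EOG").
#' @return the re-referenced `epoch_set`.
#' @export
common_average_reference <- function(epochs,
                                     exclude = grep("EOG", epochs$channel_labels,
                                                    value = TRUE)) {
  stopifnot(inherits(epochs, "epoch_set"))
  inc <- which(!(epochs$channel_labels %in% exclude))
  if (length(inc) < 2) stop("need at least 2 scalp channels to re-reference")
  for (i in seq_len(n_trials(epochs))) {
    avg <- colMeans(epochs$data[i, inc, , drop = FALSE][1, , ])
    epochs$data[i, inc, ] <- sweep(epochs$data[i, inc, , drop = TRUE], 2, avg)
  }
  epochs
}

#' Write the rejection log as TSV
#' @param epochs an `epoch_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rejection_log <- function(epochs, path) {
  write.table(epochs$rejected, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
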