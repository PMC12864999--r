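#' Hanning-taper time-frequency decomposition
#'
#' Short-time Fourier power with a fixed-length Hanning taper (default 500 ms)
#' centred at each output time point (default -3.1 to +2.2 s in 100 ms
#' steps), evaluated at integer frequencies 1-40 Hz. The 300 ms of epoch
#' retained outside the output range serves purely as padding for the window
#' edges. Power is scaled so a pure sinusoid of amplitude A yields A^2/2 at
#' its frequency bin.
#'
#' @param epochs an `epoch_set` (rejected trials are excluded).
#' @param window_len taper length in seconds (default 0.5).
#' @param step output time step in seconds (default 0.1).
#' @param freqs frequency bins in Hz (default 1:40).
#' @param times output time points in seconds (default the full grid
#'   `seq(-3.1, 2.2, by = step)` clipped to what the padding allows).
#' @param channels channel labels to decompose (default all).
#' @param average average power over trials (default TRUE).
#' @return object of class `tfr_volume`: list with `power` (channels x
#'   frequencies x times, or trials x channels x frequencies x times when
#'   `average = FALSE`), `freqs`, `times`, `channel_labels`,
#'   `baseline_mode = "raw"`, `n_trials`.
#' @export
tfr_hanning <- function(epochs, window_len = 0.5, step = 0.1, freqs = 1:40,
                        times = NULL, channels = NULL, average = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$sampling_rate
  W <- round(window_len * fs)
  half <- (W - 1) / 2
  if (is.null(times)) {
    lo <- max(-3.1, epochs$times_s[1] + half / fs)
    hi <- min(2.2, epochs$times_s[length(epochs$times_s)] - half / fs)
    times <- seq(ceiling(lo / step) * step, hi, by = step)
  }
  if (is.null(channels)) channels <- epochs$channel_labels
  ci <- match(channels, epochs$channel_labels)
  if (anyNA(ci)) stop("unknown channel(s): ",
                      paste(channels[is.na(ci)], collapse = ", "))
  centre <- round((times - epochs$times_s[1]) * fs) + 1L
  first <- centre - floor(half)
  if (any(first < 1L) || any(first + W - 1L > length(epochs$times_s)))
    stop("requested times whose window exceeds the padded epoch")
  idx <- outer(first, 0:(W - 1L), `+`)       # n_times x W sample indices

  win <- 0.5 - 0.5 * cos(2 * pi * (0:(W - 1)) / (W - 1))
  ph <- outer((0:(W - 1)) / fs, 2 * pi * freqs)
  Bc <- (cos(ph) * win) * (2 / sum(win))
  Bs <- (sin(ph) * win) * (2 / sum(win))

  trials <- clean_trials(epochs)
  nt <- length(trials)
  nts <- length(times)
  nchs <- length(ci)
  pow <- array(0, c(nt, nchs, length(freqs), nts))
  iv <- as.vector(idx)
  for (k in seq_len(nt)) {
    A <- epochs$data[trials[k], ci, , drop = FALSE]
    dim(A) <- dim(A)[2:3]                  # channels x samples
    M <- matrix(A[, iv, drop = FALSE], nchs * nts, W)
    re <- M %*% Bc
    im <- M %*% Bs
    # rows ordered channel-fastest, then time; reorder to ch x freq x time
    pow[k, , , ] <- aperm(array(re^2 + im^2, c(nchs, nts, length(freqs))),
                          c(1, 3, 2)) / 2
  }
  if (average) {
    pw <- apply(pow, c(2, 3, 4), mean)
    dimnames(pw) <- list(channels, freqs, NULL)
  } else {
    pw <- pow
    dimnames(pw) <- list(NULL, channels, freqs, NULL)
  }
  structure(list(power = pw, freqs = freqs, times = times,
                 channel_labels = channels, baseline_mode = "raw",
                 baseline_window = NULL, n_trials = nt),
            class = "tfr_volume")
}

#' @export
print.tfr_volume <- function(x, ...) {
  cat(sprintf("TFR volume (%s): %d channels x %d freqs (%g-%g Hz) x %d times (%.2f..%.2f s), %d trial(s)\n",
              x$baseline_mode, length(x$channel_labels), length(x$freqs),
              min(x$freqs), max(x$freqs), length(x$times), min(x$times),
              max(x$times), x$n_trials))
  invisible(x)
}

#' Percent-change baseline normalization
#'
#' Re-expresses power as the relative change in percent from the pre-trial
#' baseline: `100 * (P(ch,f,t) - B(ch,f)) / B(ch,f)` where B is the mean of
#' trial-averaged power over the baseline window (default -3.1 to -2.1 s,
#' before stimulation onset).
#'
#' @param tfr a raw, trial-averaged `tfr_volume`.
#' @param baseline numeric length-2 window in seconds.
#' @return a `tfr_volume` with `baseline_mode = "percent_change"`.
#' @export
baseline_percent_change <- function(tfr, baseline = c(-3.1, -2.1)) {
  stopifnot(inherits(tfr, "tfr_volume"))
  if (tfr$baseline_mode != "raw") stop("tfr is already baseline-normalized")
  if (length(dim(tfr$power)) == 4L)
    stop("baseline normalization expects trial-averaged power")
  bi <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (length(bi) == 0) stop("baseline window outside the time axis")
  B <- apply(tfr$power[, , bi, drop = FALSE], c(1, 2), mean)
  if (any(B <= 0)) {
    bad <- which(B <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive baseline power at channel %s, %s Hz",
                 tfr$channel_labels[bad[1]], tfr$freqs[bad[2]]))
  }
  tfr$power <- 100 * sweep(sweep(tfr$power, c(1, 2), B, `-`), c(1, 2), B, `/`)
  tfr$baseline_mode <- "percent_change"
  tfr$baseline_window <- baseline
  tfr
}

# discrete prolate spheroidal (Slepian) tapers via the standard symmetric
# tridiagonal eigenproblem; cached per (n, nw, k)
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.entrainr_cache[[key]])) return(.entrainr_cache[[key]])
  w <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(i + 1, i + 1)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                   # unit energy, positive mean sign
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0 && j %% 2 == 1) tap[, j] <- -tap[, j]
  }
  .entrainr_cache[[key]] <- tap
  tap
}

#' Multitaper resting-state power spectrum
#'
#' Subject-level power spectrum from short resting epochs: per epoch, power
#' at integer frequencies 1-40 Hz is estimated with DPSS (Slepian) multitapers
#' providing +-`smoothing` Hz of spectral smoothing, averaged over tapers and
#' epochs.
#'
#' @param epochs an `epoch_set` of resting epochs (default 2 s long; rejected
#'   epochs are excluded).
#' @param freqs frequency grid in Hz (default 1:40).
#' @param smoothing half-bandwidth of spectral smoothing in Hz (default 2).
#' @return object of class `power_spectrum`: list with `power` (channels x
#'   frequencies), `freqs`, `channel_labels`, `n_epochs_averaged`, `method`.
#' @export
resting_spectrum <- function(epochs, freqs = 1:40, smoothing = 2) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- clean_trials(epochs)
  if (length(keep) == 0) stop("all epochs rejected; no spectrum to compute")
  fs <- epochs$sampling_rate
  n <- dim(epochs$data)[3]
  T_s <- n / fs
  nw <- max(1, smoothing * T_s)            # time-bandwidth product
  k <- max(1, floor(2 * nw - 1))
  tap <- dpss_tapers(n, nw, k)
  ph <- outer((0:(n - 1)) / fs, 2 * pi * freqs)
  # unit-energy tapers: eigenspectra |sum h x e^-iwt|^2, averaged over tapers
  nch <- length(epochs$channel_labels)
  pow <- matrix(0, nch, length(freqs))
  for (j in seq_len(k)) {
    Bc <- cos(ph) * tap[, j]
    Bs <- sin(ph) * tap[, j]
    for (tr in keep) {
      x <- epochs$data[tr, , , drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, 1, n)
      re <- x %*% Bc
      im <- x %*% Bs
      pow <- pow + (re^2 + im^2) / 2
    }
  }
  pow <- pow / (k * length(keep))
  dimnames(pow) <- list(epochs$channel_labels, freqs)
  structure(list(power = pow, freqs = freqs,
                 channel_labels = epochs$channel_labels,
                 n_epochs_averaged = length(keep),
                 method = sprintf("dpss multitaper, +-%g Hz smoothing, %d tapers",
                                  smoothing, k)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %d channels x %d freqs (%g-%g Hz), %d epoch(s); %s\n",
              length(x$channel_labels), length(x$freqs), min(x$freqs),
              max(x$freqs), x$n_epochs_averaged, x$method))
  invisible(x)
}

#' Write a power spectrum as TSV (long format)
#' @param spectrum a `power_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  df <- data.frame(
    channel = rep(spectrum$channel_labels, times = length(spectrum$freqs)),
    freq_hz = rep(spectrum$freqs, each = length(spectrum$channel_labels)),
    power = as.vector(spectrum$power))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
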