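#' Configuration for a synthetic entrainment cohort
#'
#' Defines the study conditions the generator emulates: a between-subjects
#' design with theta (5 Hz), alpha (9 Hz), arhythmic control and
#' no-entrainment (NE) groups, 3 runs of 47 encoding trials, 64-channel
#' 500 Hz EEG, and recognition behaviour generated from an equal-variance
#' signal-detection model whose group-level d-prime distributions default to
#' the reported group summaries (theta 1.28/0.55, alpha 1.46/0.60, control
#' 1.18/0.50, NE 1.27/0.53).
#'
#' @param groups character subset of `c("theta", "alpha", "control", "ne")`.
#' @param k_per_group participants per group.
#' @param runs experimental runs (default 3).
#' @param encoding_trials_per_run encoding trials per run (default 47); each
#'   run's recognition phase has twice as many trials (old + recombined).
#' @param sampling_rate EEG sampling rate in Hz (default 500).
#' @param channel_labels channel names; defaults to the packaged 64-channel
#'   layout (60 scalp + 4 EOG).
#' @param entrain_amplitude amplitude (uV) of the entrained narrow-band
#'   component at its occipital peak.
#' @param entrain_ramp_tau time constant (s) of the exponential build-up of
#'   the entrained component (entrainment develops over time and plateaus).
#' @param noise_exponent chi of the 1/f^chi background noise spectrum.
#' @param noise_sd standard deviation (uV) of the background noise.
#' @param alpha_amplitude amplitude (uV) of ongoing ~10 Hz alpha with random
#'   phase over posterior channels.
#' @param evoked_amplitude amplitude (uV) of the damped post-stimulus evoked
#'   transient.
#' @param dprime_mean_sd_per_group named list `group -> c(mean, sd)` of the
#'   group-level d-prime distribution.
#' @param criterion_c signal-detection response criterion (default 1.1,
#'   conservative bias matching the reported hit/false-alarm rates).
#' @param artifact_rates named numeric `c(jump=, muscle=, blink=)` per-trial
#'   injection probabilities (defaults 0).
#' @param miss_rate probability that a recognition response is missed (no
#'   button press within the 3 s response window).
#' @param encoding_accuracy probability of a correct animal-categorization
#'   response during encoding.
#' @param seed integer master seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(groups = c("theta", "alpha", "control", "ne"),
                          k_per_group = 35,
                          runs = 3,
                          encoding_trials_per_run = 47,
                          sampling_rate = 500,
                          channel_labels = electrode_layout_1020()$label,
                          entrain_amplitude = 6,
                          entrain_ramp_tau = 0.3,
                          noise_exponent = 1,
                          noise_sd = 10,
                          alpha_amplitude = 3,
                          evoked_amplitude = 5,
                          dprime_mean_sd_per_group = list(
                            theta = c(1.28, 0.55), alpha = c(1.46, 0.60),
                            control = c(1.18, 0.50), ne = c(1.27, 0.53)),
                          criterion_c = 1.1,
                          artifact_rates = c(jump = 0, muscle = 0, blink = 0),
                          miss_rate = 0.02,
                          encoding_accuracy = 0.95,
                          seed = 1L) {
  groups <- match.arg(groups, c("theta", "alpha", "control", "ne"),
                      several.ok = TRUE)
  stopifnot(k_per_group >= 1, runs >= 1, encoding_trials_per_run >= 1,
            sampling_rate > 0, entrain_amplitude >= 0, entrain_ramp_tau > 0,
            noise_sd > 0, criterion_c > -Inf)
  if (!all(names(dprime_mean_sd_per_group) %in% c("theta", "alpha", "control", "ne")))
    stop("unknown group in dprime_mean_sd_per_group")
  rates <- c(jump = 0, muscle = 0, blink = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (any(rates < 0 | rates > 1)) stop("artifact_rates must be probabilities")
  structure(list(
    groups = groups, k_per_group = k_per_group, runs = runs,
    encoding_trials_per_run = encoding_trials_per_run,
    sampling_rate = sampling_rate, channel_labels = channel_labels,
    entrain_amplitude = entrain_amplitude, entrain_ramp_tau = entrain_ramp_tau,
    noise_exponent = noise_exponent, noise_sd = noise_sd,
    alpha_amplitude = alpha_amplitude, evoked_amplitude = evoked_amplitude,
    dprime_mean_sd_per_group = dprime_mean_sd_per_group,
    criterion_c = criterion_c, artifact_rates = rates,
    miss_rate = miss_rate, encoding_accuracy = encoding_accuracy,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Stimulation frequency of an experimental group
#'
#' @param group one of `"theta"`, `"alpha"`, `"control"`, `"ne"`.
#' @return frequency in Hz (5 or 9), or `NA` for the arhythmic control and the
#'   unstimulated NE group.
#' @export
group_frequency <- function(group) {
  switch(match.arg(group, c("theta", "alpha", "control", "ne")),
         theta = 5, alpha = 9, control = NA_real_, ne = NA_real_)
}

# 1/f^chi background: spectrally shaped white noise, columns ~ channels,
# approximately unit standard deviation
pink_noise <- function(n, nch, chi = 1) {
  w <- matrix(rnorm(n * nch), n, nch)
  if (chi == 0) return(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)                      # two-sided FFT bin frequencies
  shape <- c(0, f[-1]^(-chi / 2))
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / n
  x / sd(as.vector(x))
}

# spatial weight profiles over the layout (unit peak)
spatial_weights <- function(labels, centre_labels, sigma) {
  layout <- electrode_layout_1020()
  pos <- layout[match(labels, layout$label), c("x", "y")]
  cpos <- layout[match(centre_labels, layout$label), c("x", "y")]
  d2 <- vapply(seq_along(labels), function(i) {
    if (is.na(pos$x[i])) return(Inf)
    min((pos$x[i] - cpos$x)^2 + (pos$y[i] - cpos$y)^2)
  }, numeric(1))
  exp(-d2 / sigma^2)
}

#' Simulate one EEG trial segment
#'
#' One epoch spanning -3.4 s to +2.5 s around stimulus onset, containing
#' (a) 1/f^chi background noise per channel, (b) ongoing ~10 Hz alpha with
#' random phase over posterior channels, (c) for the entrainment groups a
#' narrow-band component at the group frequency during the stimulation
#' interval (-2.1 s to the group's gap before onset), rising exponentially
#' toward a plateau and spatially peaked at O1/O2/Oz (the arhythmic control
#' receives the mean-removed chained-cycle luminance drive instead), and
#' (d) a damped evoked transient after stimulus onset. The NE group has no
#' component (c).
#'
#' @param config a [cohort_config()].
#' @param group group id.
#' @param seed optional integer seed (same seed, bit-identical segment).
#' @return channels x samples matrix with attributes `times_s`,
#'   `channel_labels` and `sampling_rate`.
#' @export
simulate_eeg_trial <- function(config, group, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group, c("theta", "alpha", "control", "ne"))
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sampling_rate
  n <- round(5.9 * fs)
  t <- -3.4 + (seq_len(n) - 1) / fs
  labels <- config$channel_labels
  nch <- length(labels)

  x <- t(pink_noise(n, nch, config$noise_exponent)) * config$noise_sd

  post_w <- spatial_weights(labels, c("O1", "O2", "Oz", "POz", "Pz"), 0.45)
  occ_w <- spatial_weights(labels, c("O1", "O2", "Oz"), 0.3)

  # ongoing alpha, random phase per trial
  x <- x + outer(post_w * config$alpha_amplitude,
                 cos(2 * pi * 10 * t + runif(1, 0, 2 * pi)))

  # entrained component during the stimulation interval
  if (group %in% c("theta", "alpha")) {
    f <- group_frequency(group)
    gap_s <- post_stimulation_gap(f) / 1000
    on <- t >= -2.1 & t <= -gap_s
    env <- (1 - exp(-(t[on] + 2.1) / config$entrain_ramp_tau))
    drive <- sin(2 * pi * f * (t[on] + 2.1)) * env * config$entrain_amplitude
    x[, on] <- x[, on] + outer(occ_w, drive)
  } else if (group == "control") {
    gap_s <- 0.05
    cycles <- draw_arhythmic_cycles(2, arhythmic_frequency_pool())
    on <- t >= -2.1 & t <= -gap_s
    tt <- t[on] + 2.1
    onsets <- cumsum(c(0, 1 / cycles))
    idx <- findInterval(tt, onsets, rightmost.closed = TRUE)
    inside <- idx >= 1 & idx <= length(cycles)
    drv <- numeric(length(tt))
    drv[inside] <- (1 - cos(2 * pi * cycles[idx[inside]] *
                              (tt[inside] - onsets[idx[inside]]))) / 2 - 0.5
    env <- (1 - exp(-tt / config$entrain_ramp_tau))
    x[, on] <- x[, on] +
      outer(occ_w, 2 * config$entrain_amplitude * drv * env)
  }

  # damped evoked transient after stimulus onset
  post <- t >= 0
  x[, post] <- x[, post] +
    outer(post_w, config$evoked_amplitude *
            exp(-t[post] / 0.15) * sin(2 * pi * 8 * t[post]))

  structure(x, times_s = t, channel_labels = labels, sampling_rate = fs,
            dimnames = list(labels, NULL))
}

#' Inject jump, muscle and blink artifacts into a trial segment
#'
#' With the stated per-type probabilities, superimposes (a) a step
#' discontinuity across scalp channels ("jump"), (b) a 200 ms high-frequency
#' (30-40 Hz) burst with random per-channel gains ("muscle"), and (c) a slow
#' 400 ms frontal deflection ("blink"). Returns the contaminated segment and
#' a log of injected artifact types and latencies.
#'
#' @param segment channels x samples matrix from [simulate_eeg_trial()].
#' @param artifact_rates named probabilities `c(jump=, muscle=, blink=)`.
#' @param seed optional integer seed.
#' @param jump_amplitude,muscle_amplitude,blink_amplitude injected amplitudes
#'   in uV.
#' @return list with `segment` and `log` (data.frame `type`, `latency_s`).
#' @export
inject_artifacts <- function(segment, artifact_rates, seed = NULL,
                             jump_amplitude = 500, muscle_amplitude = 100,
                             blink_amplitude = 200) {
  if (!is.null(seed)) set.seed(seed)
  t <- attr(segment, "times_s")
  labels <- attr(segment, "channel_labels")
  fs <- attr(segment, "sampling_rate")
  n <- ncol(segment)
  rates <- c(jump = 0, muscle = 0, blink = 0)
  rates[names(artifact_rates)] <- artifact_rates
  log <- data.frame(type = character(0), latency_s = numeric(0))
  scalp <- !grepl("EOG", labels)

  if (runif(1) < rates[["jump"]]) {
    at <- sample.int(n - 1, 1)
    segment[scalp, (at + 1):n] <- segment[scalp, (at + 1):n] + jump_amplitude
    log <- rbind(log, data.frame(type = "jump", latency_s = t[at]))
  }
  if (runif(1) < rates[["muscle"]]) {
    len <- round(0.2 * fs)
    at <- sample.int(n - len, 1)
    tt <- (seq_len(len) - 1) / fs
    burst <- rowSums(vapply(runif(5, 30, 40), function(f)
      sin(2 * pi * f * tt + runif(1, 0, 2 * pi)), numeric(len))) / sqrt(5)
    burst <- burst * (0.5 - 0.5 * cos(2 * pi * seq_len(len) / len))  # taper
    gains <- runif(sum(scalp), 0.5, 1) * muscle_amplitude
    segment[scalp, at:(at + len - 1)] <-
      segment[scalp, at:(at + len - 1)] + outer(gains, burst)
    log <- rbind(log, data.frame(type = "muscle", latency_s = t[at]))
  }
  if (runif(1) < rates[["blink"]]) {
    len <- round(0.4 * fs)
    at <- sample.int(n - len, 1)
    shape <- sin(pi * seq_len(len) / len) * blink_amplitude
    frontal <- grepl("^(Fp|AF|VEOG)", labels)
    segment[frontal, at:(at + len - 1)] <-
      segment[frontal, at:(at + len - 1)] + matrix(shape, sum(frontal), len,
                                                   byrow = TRUE)
    log <- rbind(log, data.frame(type = "blink", latency_s = t[at]))
  }
  list(segment = segment, log = log)
}

#' Simulate recognition behaviour for one participant
#'
#' Draws the participant's true sensitivity from the group's Normal(M, SD)
#' truncated at 0, then generates the recognition table under the
#' equal-variance signal-detection model: familiarity of an old pair is
#' Normal(d', 1), of a recombined pair Normal(0, 1); the response is "old"
#' when familiarity exceeds the criterion c. Reaction times are
#' shifted-lognormal; responses slower than 3 s count as missed.
#'
#' @param config a [cohort_config()].
#' @param group group id.
#' @param seed optional integer seed.
#' @return list with `trials` (data.frame: `run`, `trial`, `status`,
#'   `response`, `rt_ms`, `outcome`), `encoding` (data.frame: `run`, `trial`,
#'   `correct`), and `true_dprime`.
#' @export
simulate_behavior <- function(config, group, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group, c("theta", "alpha", "control", "ne"))
  if (!is.null(seed)) set.seed(seed)
  ms <- config$dprime_mean_sd_per_group[[group]]
  if (is.null(ms)) stop("no d-prime parameters for group ", group)
  repeat {                                # truncation at 0
    dp <- rnorm(1, ms[1], ms[2])
    if (dp >= 0) break
  }
  cc <- config$criterion_c
  n_enc <- config$encoding_trials_per_run
  out <- lapply(seq_len(config$runs), function(run) {
    status <- sample(rep(c("old", "new"), n_enc))
    fam <- ifelse(status == "old", rnorm(2 * n_enc, dp, 1),
                  rnorm(2 * n_enc, 0, 1))
    resp <- ifelse(fam > cc, "old", "new")
    rt <- 300 + rlnorm(2 * n_enc, log(700), 0.5)
    missed <- rt > 3000 | runif(2 * n_enc) < config$miss_rate
    resp[missed] <- NA
    outcome <- ifelse(missed, "missed",
               ifelse(status == "old" & resp == "old", "hit",
               ifelse(status == "old", "miss",
               ifelse(resp == "old", "fa", "cr"))))
    data.frame(run = run, trial = seq_len(2 * n_enc), status = status,
               response = resp, rt_ms = rt, outcome = outcome)
  })
  enc <- data.frame(
    run = rep(seq_len(config$runs), each = n_enc),
    trial = rep(seq_len(n_enc), config$runs),
    correct = runif(config$runs * n_enc) < config$encoding_accuracy)
  list(trials = do.call(rbind, out), encoding = enc, true_dprime = dp)
}

#' Simulate a full participant (EEG epochs, behaviour, ground truth)
#'
#' Generates all encoding-trial EEG segments (with artifact injection at the
#' configured rates), assembles them into an epoch set, and simulates the
#' recognition behaviour. The ground truth records the true d-prime, the true
#' entrained amplitude and the injected artifact log per trial.
#'
#' @param config a [cohort_config()].
#' @param group group id.
#' @param id participant identifier.
#' @param seed integer seed for this participant.
#' @param n_trials optional override of the total encoding trial count
#'   (defaults to `runs * encoding_trials_per_run`).
#' @return list with `epochs` (an `epoch_set`), `behavior`, `truth`.
#' @export
simulate_participant <- function(config, group, id = 1L, seed = config$seed,
                                 n_trials = NULL) {
  set.seed(seed)
  if (is.null(n_trials))
    n_trials <- config$runs * config$encoding_trials_per_run
  fs <- config$sampling_rate
  n <- round(5.9 * fs)
  nch <- length(config$channel_labels)
  dat <- array(0, c(n_trials, nch, n))
  art_log <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    seg <- simulate_eeg_trial(config, group)
    inj <- inject_artifacts(seg, config$artifact_rates)
    dat[i, , ] <- inj$segment
    art_log[[i]] <- inj$log
  }
  beh <- simulate_behavior(config, group)
  meta <- data.frame(
    trial = seq_len(n_trials),
    run = rep(seq_len(config$runs), length.out = n_trials),
    group = group, participant = id)
  epochs <- new_epoch_set(dat, sampling_rate = fs, t_start = -3.4,
                          channel_labels = config$channel_labels,
                          metadata = meta)
  truth <- list(true_dprime = beh$true_dprime,
                true_entrain_amplitude =
                  if (group %in% c("theta", "alpha")) config$entrain_amplitude else 0,
                artifact_log = art_log,
                artifact_trials = which(vapply(art_log, nrow, integer(1)) > 0))
  list(epochs = epochs, behavior = beh, truth = truth, id = id, group = group)
}

#' Simulate a continuous single-run recording with event markers
#'
#' Concatenates per-trial segments with inter-trial background noise into one
#' continuous multichannel recording, with one strictly increasing
#' stimulus-onset marker per trial. This exercises the epoching and file IO
#' paths; the trialwise generator is used for pipeline-scale simulation.
#'
#' @param config a [cohort_config()].
#' @param group group id.
#' @param n_trials number of trials in the run.
#' @param seed integer seed.
#' @return object of class `eeg_recording`: list with `data` (channels x
#'   samples), `sampling_rate`, `channel_labels`, `events` (data.frame
#'   `sample`, `time_s`, `trial`).
#' @export
simulate_run_recording <- function(config, group, n_trials = 8, seed = config$seed) {
  set.seed(seed)
  fs <- config$sampling_rate
  nch <- length(config$channel_labels)
  iti <- round(runif(n_trials + 1, 0.5, 1.5) * fs)
  segs <- vector("list", 2 * n_trials + 1)
  onsets <- integer(n_trials)
  pos <- 0L
  segs[[1]] <- t(pink_noise(iti[1], nch, config$noise_exponent)) * config$noise_sd
  pos <- pos + iti[1]
  for (i in seq_len(n_trials)) {
    seg <- simulate_eeg_trial(config, group)
    onsets[i] <- pos + round(3.4 * fs) + 1L
    segs[[2 * i]] <- unclass(seg)
    pos <- pos + ncol(seg)
    segs[[2 * i + 1]] <- t(pink_noise(iti[i + 1], nch, config$noise_exponent)) *
      config$noise_sd
    pos <- pos + iti[i + 1]
  }
  data <- do.call(cbind, segs)
  rownames(data) <- config$channel_labels
  structure(list(
    data = data, sampling_rate = fs, channel_labels = config$channel_labels,
    events = data.frame(sample = onsets, time_s = (onsets - 1) / fs,
                        trial = seq_len(n_trials))
  ), class = "eeg_recording")
}

#' Simulate resting-state epochs with individual spectral peaks
#'
#' 2 s epochs of 1/f background plus an alpha oscillation centred on the
#' participant's individual alpha frequency (IAF) and a weaker theta
#' component at the individual theta frequency (ITF), both
#' posterior-weighted. The oscillation frequency drifts slightly from epoch
#' to epoch (SD 0.4 Hz), as endogenous rhythms do, so the subject-level
#' spectrum shows a hump centred on the individual frequency rather than a
#' line. Feeds the multitaper spectrum and IAF/ITF extraction analyses.
#'
#' @param config a [cohort_config()].
#' @param iaf_hz,itf_hz individual alpha/theta peak frequencies.
#' @param n_epochs number of 2 s epochs (default 90, i.e. 3 min).
#' @param seed optional integer seed.
#' @return an `epoch_set` with epochs spanning 0-2 s.
#' @export
simulate_resting_epochs <- function(config, iaf_hz = 10, itf_hz = 5,
                                    n_epochs = 90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sampling_rate
  n <- round(2 * fs)
  t <- (seq_len(n) - 1) / fs
  labels <- config$channel_labels
  nch <- length(labels)
  post_w <- spatial_weights(labels, c("O1", "O2", "Oz", "POz", "Pz"), 0.45)
  dat <- array(0, c(n_epochs, nch, n))
  for (i in seq_len(n_epochs)) {
    x <- t(pink_noise(n, nch, config$noise_exponent)) * config$noise_sd
    x <- x + outer(post_w * config$alpha_amplitude * 3,
                   cos(2 * pi * rnorm(1, iaf_hz, 0.4) * t +
                         runif(1, 0, 2 * pi)))
    x <- x + outer(post_w * config$alpha_amplitude * 2,
                   cos(2 * pi * rnorm(1, itf_hz, 0.4) * t +
                         runif(1, 0, 2 * pi)))
    dat[i, , ] <- x
  }
  new_epoch_set(dat, sampling_rate = fs, t_start = 0, channel_labels = labels,
                metadata = data.frame(trial = seq_len(n_epochs)))
}
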