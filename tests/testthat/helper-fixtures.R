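# shared fixtures: small channel sets, quick epoch builders, and the
# independent fine-grid quadrature oracle for the JZS Bayes factor

occipital_set <- c("O1", "O2", "Oz")

posterior_set <- c("O1", "O2", "Oz", "POz", "Pz", "P3", "P4", "PO3", "PO4",
                   "Cz", "HEOGL")

small_config <- function(...) {
  cohort_config(channel_labels = posterior_set, ...)
}

# epoch set of deterministic sinusoids + optional noise, spanning the study
# window at 500 Hz
sinusoid_epochs <- function(freq, amplitude = 1, n_trials = 3,
                            channels = c("O1", "O2"), noise_sd = 0,
                            t_start = -3.4, duration = 5.9, fs = 500,
                            seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  t <- t_start + (seq_len(n) - 1) / fs
  dat <- array(0, c(n_trials, length(channels), n))
  for (i in seq_len(n_trials))
    for (j in seq_along(channels))
      dat[i, j, ] <- amplitude * sin(2 * pi * freq * t) +
        rnorm(n, 0, noise_sd)
  new_epoch_set(dat, fs, t_start, channels)
}

# simulate one participant's trial epochs without behaviour (fast path);
# seed = NULL continues the caller's RNG stream
participant_epochs <- function(config, group, n_trials, seed) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sampling_rate
  dat <- array(0, c(n_trials, length(config$channel_labels), round(5.9 * fs)))
  for (i in seq_len(n_trials))
    dat[i, , ] <- simulate_eeg_trial(config, group)
  new_epoch_set(dat, fs, -3.4, config$channel_labels)
}

# participant-level percent-change TFR restricted to baseline + test windows
participant_pc_tfr <- function(config, group, n_trials, seed,
                               test_window = c(-1.1, -0.1)) {
  ep <- participant_epochs(config, group, n_trials, seed)
  times <- c(seq(-3.1, -2.1, by = 0.1),
             seq(test_window[1], test_window[2], by = 0.1))
  tfr <- tfr_hanning(ep, times = times)
  pc <- baseline_percent_change(tfr)
  ti <- pc$times >= test_window[1] - 1e-9
  pc$power <- pc$power[, , ti, drop = FALSE]
  pc$times <- pc$times[ti]
  pc
}

# independent oracle: JZS BF by composite Simpson integration on a dense
# fixed grid of the raw effect-size scale (no variable substitution, no
# adaptive quadrature) -- the likelihood is negligible beyond |delta| = 8 at
# the sample sizes used, and the Cauchy-weighted tail out to 80 is covered by
# a coarser panel
oracle_jzs_bf <- function(t_stat, n1, n2, r = sqrt(2) / 2,
                          sidedness = "two_sided") {
  df <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  f <- function(delta)
    suppressWarnings(stats::dt(t_stat, df, ncp = delta * sqrt(neff))) *
    stats::dcauchy(delta, 0, r)
  simpson <- function(lo, hi, n) {          # n odd grid points
    x <- seq(lo, hi, length.out = n)
    h <- x[2] - x[1]
    w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
    sum(w * f(x)) * h / 3
  }
  num <- switch(sidedness,
    two_sided = simpson(-80, -8, 2001) + simpson(-8, 8, 16001) +
      simpson(8, 80, 2001),
    one_sided_greater = 2 * (simpson(0, 8, 16001) + simpson(8, 80, 2001)),
    one_sided_less = 2 * (simpson(-80, -8, 2001) + simpson(-8, 0, 16001)))
  num / stats::dt(t_stat, df)
}
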