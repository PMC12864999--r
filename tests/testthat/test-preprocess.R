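test_that("bandpass keeps the pass band and suppresses stop band and DC", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  x60 <- sin(2 * pi * 60 * t)
  y60 <- bandpass(matrix(x60, 1), 0.5, 40, fs)[1, ]
  expect_lt(rms(y60), 0.1 * rms(x60))
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass(matrix(x10, 1), 0.5, 40, fs)[1, ]
  expect_equal(rms(y10), rms(x10), tolerance = 0.05)
  ydc <- bandpass(matrix(rep(100, length(t)), 1), 0.5, 40, fs)[1, ]
  mid <- seq(length(t) / 4, 3 * length(t) / 4)   # past the edge transients
  expect_lt(abs(mean(ydc[mid])), 1)
  expect_error(bandpass(matrix(x10, 1), 0.5, 300, fs), "Nyquist")
})

test_that("epoching maps markers to the -3.4..2.5 s window and flags edges", {
  cc <- small_config()
  rec <- simulate_run_recording(cc, "ne", n_trials = 2, seed = 3)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data)[3], 2950)
  expect_equal(ep$times_s[1], -3.4)
  # onset sample index = -t_start * fs + 1
  expect_equal(which.min(abs(ep$times_s)), 3.4 * 500 + 1)
  # empty marker list: empty epoch set, no error
  e0 <- epoch_recording(rec, events = integer(0))
  expect_equal(n_trials(e0), 0)
  # marker too close to the edge is flagged, not dropped
  e1 <- epoch_recording(rec, events = c(100L, rec$events$sample[1]))
  expect_equal(n_trials(e1), 2)
  expect_equal(e1$rejected$trial, 1L)
  expect_equal(e1$rejected$reason, "edge")
})

test_that("injected jumps are flagged as jumps; clean data stays clean", {
  cc <- small_config()
  n_tr <- 24
  set.seed(11)
  dat <- array(0, c(n_tr, length(posterior_set), 2950))
  for (i in seq_len(n_tr)) {
    seg <- simulate_eeg_trial(cc, "ne")
    if (i %in% c(5, 17)) seg <- inject_artifacts(seg, c(jump = 1))$segment
    dat[i, , ] <- seg
  }
  ep <- new_epoch_set(dat, 500, -3.4, posterior_set)
  ep <- zscore_artifact_reject(ep)
  expect_setequal(ep$rejected$trial, c(5, 17))
  expect_true(all(ep$rejected$reason == "jump"))
  # infinite thresholds reject nothing
  ep2 <- zscore_artifact_reject(new_epoch_set(dat, 500, -3.4, posterior_set),
                                jump_threshold = Inf, muscle_threshold = Inf)
  expect_equal(nrow(ep2$rejected), 0)
  expect_error(zscore_artifact_reject(
    new_epoch_set(dat[1, , , drop = FALSE], 500, -3.4, posterior_set)),
    "fewer than 2")
})

test_that("muscle bursts are flagged and rejection is permutation-equivariant", {
  cc <- small_config()
  n_tr <- 16
  set.seed(21)
  dat <- array(0, c(n_tr, length(posterior_set), 2950))
  for (i in seq_len(n_tr)) {
    seg <- simulate_eeg_trial(cc, "ne")
    if (i == 7) seg <- inject_artifacts(seg, c(muscle = 1))$segment
    dat[i, , ] <- seg
  }
  ep <- zscore_artifact_reject(new_epoch_set(dat, 500, -3.4, posterior_set))
  expect_true(7 %in% ep$rejected$trial)
  # reorder trials: flags move with the trials
  perm <- sample(n_tr)
  epp <- zscore_artifact_reject(
    new_epoch_set(dat[perm, , ], 500, -3.4, posterior_set))
  expect_setequal(match(ep$rejected$trial, perm), epp$rejected$trial)
})

test_that("common average reference zeroes the scalp mean and is idempotent", {
  cc <- small_config()
  ep <- participant_epochs(cc, "theta", 3, seed = 31)
  car <- common_average_reference(ep)
  scalp <- which(!grepl("EOG", posterior_set))
  for (i in 1:3) {
    m <- colMeans(car$data[i, scalp, ])
    expect_lt(max(abs(m)), 1e-10)
  }
  # EOG untouched
  eog <- which(grepl("EOG", posterior_set))
  expect_equal(car$data[, eog, ], ep$data[, eog, ])
  # idempotent
  car2 <- common_average_reference(car)
  expect_equal(car2$data, car$data, tolerance = 1e-12)
  expect_error(common_average_reference(ep, exclude = posterior_set),
               "at least 2")
})
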