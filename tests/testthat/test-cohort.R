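test_that("simulated trials have the study geometry and are seed-deterministic", {
  cc <- small_config()
  seg <- simulate_eeg_trial(cc, "theta", seed = 4)
  expect_equal(dim(seg), c(length(posterior_set), round(5.9 * 500)))
  t <- attr(seg, "times_s")
  expect_equal(t[1], -3.4)
  expect_equal(t[length(t)], 2.5 - 1 / 500)
  expect_true(all(is.finite(seg)))
  seg2 <- simulate_eeg_trial(cc, "theta", seed = 4)
  expect_identical(seg, seg2)
  expect_error(simulate_eeg_trial(cc, "gamma"), "arg")
})

test_that("the entrained component is band-specific and occipitally peaked", {
  cc <- small_config(entrain_amplitude = 12, noise_sd = 3)
  band_power <- function(seg, f, ch) {
    t <- attr(seg, "times_s")
    on <- t >= -1.1 & t <= -0.1
    x <- seg[ch, on]
    n <- length(x)
    sp <- Mod(fft(x - mean(x)))^2
    hz <- (seq_len(n) - 1) * 500 / n
    mean(sp[hz >= f - 1 & hz <= f + 1])
  }
  p5 <- p9 <- pO <- pC <- 0
  for (s in 1:10) {
    seg <- simulate_eeg_trial(cc, "theta", seed = s)
    p5 <- p5 + band_power(seg, 5, 1)
    p9 <- p9 + band_power(seg, 9, 1)
    pO <- pO + band_power(seg, 5, which(posterior_set == "Oz"))
    pC <- pC + band_power(seg, 5, which(posterior_set == "Cz"))
  }
  expect_gt(p5, 3 * p9)   # stimulated band, not the other group's band
  expect_gt(pO, 2 * pC)   # occipital focus
})

test_that("with zero amplitude theta and NE trials are indistinguishable", {
  cc <- small_config(entrain_amplitude = 0)
  bp <- function(group, s) {
    seg <- simulate_eeg_trial(cc, group, seed = s)
    t <- attr(seg, "times_s")
    x <- seg[1, t >= -1.1 & t <= -0.1]
    sp <- Mod(fft(x - mean(x)))^2
    hz <- (seq_along(x) - 1) * 500 / length(x)
    mean(sp[hz >= 4 & hz <= 6])
  }
  a <- vapply(1:25, function(s) bp("theta", s), numeric(1))
  b <- vapply(26:50, function(s) bp("ne", s), numeric(1))
  expect_gt(stats::wilcox.test(a, b)$p.value, 0.01)
})

test_that("behaviour follows the equal-variance SDT generative model", {
  cc <- small_config()
  b <- simulate_behavior(cc, "alpha", seed = 1)
  expect_equal(nrow(b$trials), cc$runs * 2 * cc$encoding_trials_per_run)
  expect_setequal(unique(b$trials$status), c("old", "new"))
  expect_gte(b$true_dprime, 0)
  # d' = 0, c = 0: hit and FA rates both ~0.5
  cc0 <- small_config(
    dprime_mean_sd_per_group = list(ne = c(0, 1e-9)), criterion_c = 0,
    miss_rate = 0)
  hits <- fas <- 0
  for (s in 1:12) {
    tr <- simulate_behavior(cc0, "ne", seed = s)$trials
    hits <- hits + mean(tr$outcome[tr$status == "old"] == "hit", na.rm = TRUE)
    fas <- fas + mean(tr$outcome[tr$status == "new"] == "fa", na.rm = TRUE)
  }
  expect_equal(hits / 12, 0.5, tolerance = 0.06)
  expect_equal(fas / 12, 0.5, tolerance = 0.06)
  # degenerate criterion: everything called "new"
  ccc <- small_config(criterion_c = 1e9, miss_rate = 0)
  tr <- simulate_behavior(ccc, "control", seed = 2)$trials
  expect_equal(sum(tr$outcome %in% c("hit", "fa")), 0)
})

test_that("group-level mean d-prime matches the generative target", {
  cc <- small_config()
  dp <- vapply(1:60, function(s)
    simulate_behavior(cc, "alpha", seed = s)$true_dprime, numeric(1))
  # truncated-normal mean of N(1.46, 0.6) truncated at 0 is ~1.47
  expect_equal(mean(dp), 1.46, tolerance = 3 * 0.60 / sqrt(60) + 0.02)
})

test_that("artifact injection is optional, logged, and seed-stable", {
  cc <- small_config()
  seg <- simulate_eeg_trial(cc, "ne", seed = 9)
  clean <- inject_artifacts(seg, c(jump = 0, muscle = 0, blink = 0), seed = 1)
  expect_identical(clean$segment, seg)
  expect_equal(nrow(clean$log), 0)
  j1 <- inject_artifacts(seg, c(jump = 1), seed = 2)
  j2 <- inject_artifacts(seg, c(jump = 1), seed = 2)
  expect_identical(j1$segment, j2$segment)
  expect_equal(j1$log$type, "jump")
  # the step changes the late segment by the jump amplitude
  d <- j1$segment[1, ] - seg[1, ]
  expect_setequal(round(unique(d), 6), c(0, 500))
})

test_that("continuous run recordings carry one increasing marker per trial", {
  cc <- small_config()
  rec <- simulate_run_recording(cc, "theta", n_trials = 3, seed = 5)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$events), 3)
  expect_true(all(diff(rec$events$sample) > 0))
  ep <- epoch_recording(rec)
  expect_equal(n_trials(ep), 3)
  # epoching recovers the simulated segments around each marker
  seg <- ep$data[2, , ]
  expect_equal(dim(seg), c(length(posterior_set), round(5.9 * 500)))
})
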