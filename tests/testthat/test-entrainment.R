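# build a percent-change TFR with a prescribed band/channel-averaged
# timecourse in the assessment window
pc_fixture <- function(values, times = seq(-1.1, -0.1, by = 0.1)) {
  chans <- c("O1", "O2", "Oz")
  pw <- array(0, c(3, 40, length(times)))
  for (f in 4:6) pw[, f, ] <- rep(values, each = 3)
  structure(list(power = pw, freqs = 1:40, times = times,
                 channel_labels = chans, baseline_mode = "percent_change",
                 baseline_window = c(-3.1, -2.1), n_trials = 1),
            class = "tfr_volume")
}

test_that("the 10%/500 ms criterion is applied to the late-window timecourse", {
  # constant +30%: passes with the full 1000 ms sustained
  a <- assess_entrainment(pc_fixture(rep(30, 11)), 5)
  expect_true(a$passed)
  expect_equal(a$sustained_ms, 1000)
  expect_equal(a$max_percent_change, 30)
  # +12% for only 400 ms (4 bins): fails
  b <- assess_entrainment(pc_fixture(c(12, 12, 12, 12, rep(0, 7))), 5)
  expect_false(b$passed)
  expect_equal(b$sustained_ms, 400)
  # +9.9% forever: fails (below threshold)
  c <- assess_entrainment(pc_fixture(rep(9.9, 11)), 5)
  expect_false(c$passed)
  expect_equal(c$sustained_ms, 0)
  # exactly 10% for exactly 500 ms: passes (at least semantics)
  d <- assess_entrainment(pc_fixture(c(rep(10, 5), rep(0, 6))), 5)
  expect_true(d$passed)
  expect_equal(d$sustained_ms, 500)
})

test_that("missing occipital channels or bands are errors", {
  pc <- pc_fixture(rep(30, 11))
  pc$channel_labels <- c("F1", "F2", "F3")
  expect_error(assess_entrainment(pc, 5), "occipital")
  pc2 <- pc_fixture(rep(30, 11))
  expect_error(assess_entrainment(pc2, 40), "band")
  raw <- pc_fixture(rep(30, 11))
  raw$baseline_mode <- "raw"
  expect_error(assess_entrainment(raw, 5), "percent-change")
})

test_that("the criterion passes entrained and rejects unstimulated data", {
  cc <- cohort_config(channel_labels = occipital_set)
  a <- assess_entrainment(participant_pc_tfr(cc, "theta", 25, seed = 1), 5)
  expect_true(a$passed)
  expect_gt(a$max_percent_change, 10)
  b <- assess_entrainment(participant_pc_tfr(cc, "alpha", 25, seed = 2), 9)
  expect_true(b$passed)
})

test_that("entrainment pass probability is monotone in injected amplitude", {
  rate_at <- function(amp) {
    cc <- cohort_config(channel_labels = occipital_set,
                        entrain_amplitude = amp)
    mean(vapply(1:6, function(s)
      assess_entrainment(participant_pc_tfr(cc, "theta", 12, seed = s),
                         5)$passed, logical(1)))
  }
  r <- c(rate_at(0), rate_at(3), rate_at(8))
  expect_true(all(diff(r) >= 0))
  expect_lt(r[1], 0.5)
  expect_equal(r[3], 1)
})

test_that("band peaks are extracted with lower-frequency tie-breaking", {
  chans <- posterior_electrodes()
  mk_spec <- function(peak_f, peak_amp = 5) {
    pw <- matrix(1, length(chans), 40)
    if (!is.na(peak_f)) pw[, peak_f] <- peak_amp
    structure(list(power = pw, freqs = 1:40, channel_labels = chans,
                   n_epochs_averaged = 1, method = "fixture"),
              class = "power_spectrum")
  }
  iaf <- extract_band_peak(mk_spec(10), c(8, 12))
  expect_equal(iaf$peak_frequency_hz, 10)
  expect_equal(peak_distance(iaf, 9), 1)
  itf <- extract_band_peak(mk_spec(5), c(3, 7))
  expect_equal(itf$peak_frequency_hz, 5)
  expect_equal(peak_distance(itf, 5), 0)
  # flat spectrum: lower band edge with a tie warning
  expect_warning(flat <- extract_band_peak(mk_spec(NA), c(8, 12)), "tie")
  expect_equal(flat$peak_frequency_hz, 8)
  expect_error(extract_band_peak(mk_spec(10), c(8, 12), electrodes = "XX"),
               "missing electrode")
})

test_that("IAF is recovered from simulated resting EEG", {
  cc <- small_config()
  re <- simulate_resting_epochs(cc, iaf_hz = 11, itf_hz = 5, n_epochs = 45,
                                seed = 3)
  sp <- resting_spectrum(re)
  iaf <- extract_band_peak(sp, c(8, 12),
                           electrodes = intersect(posterior_electrodes(),
                                                  posterior_set))
  expect_equal(iaf$peak_frequency_hz, 11)
})

test_that("distance-strength correlation matches cor.test and guards input", {
  set.seed(4)
  d <- runif(20, 0, 3)
  s <- -2 * d + 5
  r <- distance_strength_correlation(d, s)
  expect_equal(r$r, -1)
  s2 <- s + rnorm(20)
  r2 <- distance_strength_correlation(d, s2)
  ct <- cor.test(d, s2)
  expect_equal(r2$r, unname(ct$estimate))
  expect_equal(r2$p, ct$p.value)
  expect_error(distance_strength_correlation(rep(1, 3), c(1, 2, 3)),
               "zero variance")
  expect_error(distance_strength_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("null distances and strengths give small correlations", {
  set.seed(9)
  ps <- replicate(40, distance_strength_correlation(runif(30), runif(30))$p)
  # p-values approximately uniform: no excess of small p
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.3)
})
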