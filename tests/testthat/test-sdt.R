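mk_trials <- function(hits, misses, crs, fas, missed_old = 0, missed_new = 0) {
  data.frame(
    status = c(rep("old", hits + misses + missed_old),
               rep("new", crs + fas + missed_new)),
    response = c(rep("old", hits), rep("new", misses),
                 rep(NA, missed_old),
                 rep("new", crs), rep("old", fas), rep(NA, missed_new)))
}

test_that("rate correction applies only at the boundaries", {
  expect_equal(rate_correction(0, 47), 0.5 / 48)
  expect_equal(rate_correction(47, 47), 47.5 / 48)
  expect_equal(rate_correction(20, 47), 20 / 47)
  expect_error(rate_correction(1, 0), "zero denominator")
  expect_error(rate_correction(5, 3), "0..n")
})

test_that("d-prime follows the z-difference definition", {
  # symmetric rates: z = +-0.5 gives d' = 1 exactly
  tr <- mk_trials(hits = 69146, misses = 30854, crs = 69146, fas = 30854)
  s <- score_recognition(tr)
  expect_equal(s$hit_rate, 0.69146)
  expect_equal(s$fa_rate, 0.30854)
  expect_equal(s$dprime, 1.0, tolerance = 1e-4)
  # rates matching the reported alpha-group means: normal-quantile oracle
  tr2 <- mk_trials(hits = 61498, misses = 100000 - 61498,
                   crs = 100000 - 13900, fas = 13900)
  s2 <- score_recognition(tr2)
  expect_equal(s2$dprime, qnorm(0.61498) - qnorm(0.139))
  expect_equal(s2$dprime, 1.3771, tolerance = 1e-4)
})

test_that("missed responses leave the denominators", {
  tr <- mk_trials(hits = 30, misses = 10, crs = 35, fas = 5,
                  missed_old = 7, missed_new = 3)
  s <- score_recognition(tr)
  expect_equal(s$hits + s$misses, 40)
  expect_equal(s$crs + s$fas, 40)
  expect_equal(s$missed, 10)
  expect_equal(s$hit_rate, 30 / 40)
  # slow responses count as missed through the rt column
  tr$rt_ms <- 500
  tr$rt_ms[tr$status == "old" & !is.na(tr$response) &
             tr$response == "old"][1] <- 3500
  s2 <- score_recognition(tr)
  expect_equal(s2$hits, 29)
  expect_equal(s2$missed, 11)
  expect_error(score_recognition(mk_trials(0, 0, 5, 5, missed_old = 3)),
               "no valid old")
})

test_that("the 25% false-alarm exclusion rule is a strict threshold", {
  excl <- score_recognition(mk_trials(50, 50, 74, 26))
  expect_true(excl$excluded)          # fa_rate 0.26
  keep <- score_recognition(mk_trials(50, 50, 75, 25))
  expect_false(keep$excluded)         # fa_rate exactly 0.25
})

test_that("d-prime is antisymmetric under old/new label + response inversion", {
  tr <- mk_trials(hits = 30, misses = 12, crs = 33, fas = 9)
  s <- score_recognition(tr)
  inv <- tr
  inv$status <- ifelse(tr$status == "old", "new", "old")
  inv$response <- ifelse(is.na(tr$response), NA,
                         ifelse(tr$response == "old", "new", "old"))
  s_inv <- score_recognition(inv)
  expect_equal(s_inv$dprime, s$dprime)       # hits<->CRs, misses<->FAs
  # response inversion alone flips the sign
  flip <- tr
  flip$response <- inv$response
  expect_equal(score_recognition(flip)$dprime, -s$dprime)
})

test_that("estimated d-prime is unbiased on simulator output at study size", {
  cc <- small_config(miss_rate = 0)
  res <- t(vapply(1:40, function(s) {
    b <- simulate_behavior(cc, "control", seed = s)
    c(true = b$true_dprime, est = score_recognition(b$trials)$dprime)
  }, numeric(2)))
  bias <- mean(res[, "est"] - res[, "true"])
  expect_lt(abs(bias), 0.08)
  fit <- lm(est ~ true, as.data.frame(res))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.15)
})

test_that("NE subsampling picks the mean-closest of exactly 50 draws", {
  set.seed(6)
  scores <- c(rep(0, 44), 10)             # one outlier
  m <- ne_subsample_match(scores, target_k = 35, seed = 3)
  expect_length(m$candidate_means, 50)
  expect_length(m$indices, 35)
  # the chosen subsample is at least as close as every recorded candidate
  expect_true(all(abs(m$mean - m$full_mean) <=
                    abs(m$candidate_means - m$full_mean) + 1e-12))
  expect_lt(abs(m$mean - m$full_mean),
            max(abs(m$candidate_means - m$full_mean)))
  # identical scores: any subsample matches exactly
  m2 <- ne_subsample_match(rep(1.3, 45), seed = 1)
  expect_equal(m2$mean, m2$full_mean)
  expect_error(ne_subsample_match(rnorm(10), target_k = 35), "exceeds")
})

test_that("encoding accuracy is a simple proportion", {
  enc <- data.frame(correct = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(score_encoding_accuracy(enc), 0.75)
})

test_that("behaviour TSV round-trips through score_recognition", {
  cc <- small_config()
  b <- simulate_behavior(cc, "theta", seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_behavior_tsv(b, path, participant = "p1", group = "theta")
  back <- read.table(path, header = TRUE, sep = "\t", na.strings = "NA")
  expect_equal(score_recognition(back)$dprime,
               score_recognition(b$trials)$dprime)
})
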