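test_that("JZS quadrature agrees with the fine-grid oracle across (t, n)", {
  for (t_stat in c(-2.5, 0, 0.8, 2.1, 4)) {
    for (n in c(10, 35, 60)) {
      for (side in c("two_sided", "one_sided_greater", "one_sided_less")) {
        got <- jzs_bf_from_t(t_stat, n, n, sidedness = side)
        want <- oracle_jzs_bf(t_stat, n, n, sidedness = side)
        expect_equal(got, want, tolerance = 1e-6,
                     label = sprintf("t=%g n=%d %s", t_stat, n, side))
      }
    }
  }
})

test_that("at t = 0 the one- and two-sided Bayes factors coincide and favour H0", {
  bf2 <- jzs_bf_two_sample(1, 1, 35, 1, 1, 35, sidedness = "two_sided")
  bfg <- jzs_bf_two_sample(1, 1, 35, 1, 1, 35, sidedness = "one_sided_greater")
  expect_equal(bf2$t_stat, 0)
  expect_lt(bf2$bf10, 1)
  expect_equal(bfg$bf10, bf2$bf10, tolerance = 1e-8)
  expect_equal(bf2$bf10, oracle_jzs_bf(0, 35, 35), tolerance = 1e-6)
})

test_that("the truncation identity holds: BF+ + BF- = 2 BF two-sided", {
  for (t_stat in c(-1.2, 0.5, 2.7)) {
    g <- jzs_bf_from_t(t_stat, 20, 25, sidedness = "one_sided_greater")
    l <- jzs_bf_from_t(t_stat, 20, 25, sidedness = "one_sided_less")
    b <- jzs_bf_from_t(t_stat, 20, 25, sidedness = "two_sided")
    expect_equal(g + l, 2 * b, tolerance = 1e-7)
  }
})

test_that("the two-sided Bayes factor is monotone in |t|", {
  bfs <- vapply(c(0, 0.5, 1, 1.5, 2, 3, 4), function(t)
    jzs_bf_from_t(t, 35, 35), numeric(1))
  expect_true(all(diff(bfs) > 0))
  neg <- vapply(c(0, -1, -2, -3), function(t)
    jzs_bf_from_t(t, 35, 35), numeric(1))
  expect_true(all(diff(neg) > 0))
})

test_that("raw-vector input delegates to the summary entry point", {
  set.seed(2)
  x <- rnorm(20, 1); y <- rnorm(25)
  raw <- jzs_bf_raw(x, y, sidedness = "one_sided_greater")
  summ <- jzs_bf_two_sample(mean(x), sd(x), 20, mean(y), sd(y), 25,
                            sidedness = "one_sided_greater")
  expect_equal(raw$bf10, summ$bf10)
  expect_equal(raw$t_stat,
               t.test(x, y, var.equal = TRUE)$statistic[[1]])
})

test_that("invalid inputs are rejected", {
  expect_error(jzs_bf_two_sample(1, 0, 10, 0, 1, 10), "positive")
  expect_error(jzs_bf_two_sample(1, 1, 1, 0, 1, 10), "at least 2")
  expect_error(jzs_bf_two_sample(NaN, 1, 10, 0, 1, 10), "non-finite")
})

test_that("the sequential monitor applies the stopping rule", {
  # crossing BF >= 3 at some k stops with accept_H1 at that k
  mk_looks <- function(d) data.frame(
    k = 15:35,
    mean1 = d, sd1 = 1, mean2 = 0, sd2 = 1)
  st <- sequential_monitor(mk_looks(1.2), sidedness = "one_sided_greater")
  expect_equal(st$decision, "accept_H1")
  expect_equal(st$k_stop, st$k_trace[length(st$k_trace)])
  expect_gte(st$bf_trace[length(st$bf_trace)], 3)
  expect_true(all(st$bf_trace[-length(st$bf_trace)] < 3))
  # a flat null trace runs to the cap
  st0 <- sequential_monitor(mk_looks(0.0))
  expect_true(st0$decision %in% c("accept_H0", "max_n_reached"))
  if (st0$decision == "max_n_reached") expect_equal(st0$k_stop, 35)
  # non-contiguous k traces are rejected
  bad <- mk_looks(1)[c(1, 3), ]
  expect_error(sequential_monitor(bad), "contiguous")
})

test_that("sequential traces export as TSV", {
  looks <- data.frame(k = 15:18, mean1 = 2, sd1 = 1, mean2 = 0, sd2 = 1)
  st <- sequential_monitor(looks, sidedness = "one_sided_greater")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sequential_tsv(st, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$k, st$k_trace)
  expect_equal(back$bf10, st$bf_trace, tolerance = 1e-6)
})
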