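two_channel_graph <- function() {
  channel_neighbours(data.frame(label = c("ch1", "ch2"), x = c(0, 0.1),
                                y = c(0, 0), type = "scalp"), 0.28)
}

test_that("the packaged neighbour template is symmetric, irreflexive, connected", {
  ng <- channel_neighbours()
  adj <- ng$adjacency
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  lay <- electrode_layout_1020()
  scalp <- lay$type == "scalp"
  expect_true(all(rowSums(adj[scalp, ]) >= 1))
  expect_true(all(rowSums(adj[!scalp, ]) == 0))
  # occipital electrodes neighbour each other
  expect_true(adj["O1", "Oz"] && adj["Oz", "O2"])
})

test_that("sample-level statistics agree with stats::t.test and are degenerate-safe", {
  set.seed(1)
  dims <- c(2, 3, 4)
  ga <- array(rnorm(5 * prod(dims)), c(5, dims))
  gb <- array(rnorm(6 * prod(dims), 0.5), c(6, dims))
  st <- samplewise_stat(ga, gb, "independent_t")
  tt <- t.test(ga[, 1, 1, 1], gb[, 1, 1, 1], var.equal = TRUE)
  expect_equal(st$stat[1, 1, 1], unname(tt$statistic))
  expect_equal(st$p[1, 1, 1], tt$p.value)
  # paired t on identical groups is zero (or 0/0) everywhere
  sp <- samplewise_stat(ga, ga, "paired_t")
  expect_true(all(sp$stat == 0 | is.nan(sp$stat)))
  # F over three identical groups is ~0 everywhere
  sf <- samplewise_stat(groups = list(ga, ga, ga), kind = "F")
  expect_lt(max(sf$stat), 1e-20)
  # F agrees with aov on one voxel
  gc <- array(rnorm(5 * prod(dims), 1), c(5, dims))
  sf2 <- samplewise_stat(groups = list(ga, gb, gc), kind = "F")
  df <- data.frame(y = c(ga[, 2, 2, 2], gb[, 2, 2, 2], gc[, 2, 2, 2]),
                   g = factor(rep(1:3, c(5, 6, 5))))
  aovF <- summary(stats::aov(y ~ g, df))[[1]]$`F value`[1]
  expect_equal(sf2$stat[2, 2, 2], aovF)
  expect_error(samplewise_stat(ga, array(rnorm(24), c(2, 2, 3, 2)),
                               "independent_t"), "share axes")
  expect_error(samplewise_stat(ga, gb, "paired_t"), "equal subject")
})

test_that("clusters form under channel/frequency/time adjacency rules", {
  ng <- two_channel_graph()
  # two suprathreshold voxels on NON-neighbouring channels: 2 clusters
  ng0 <- ng
  ng0$adjacency[] <- FALSE
  stat <- array(0, c(2, 1, 3))
  p <- array(1, c(2, 1, 3))
  stat[1, 1, 2] <- 4; stat[2, 1, 2] <- 4
  p[1, 1, 2] <- 0.01; p[2, 1, 2] <- 0.01
  dimnames(stat)[[1]] <- dimnames(p)[[1]] <- c("ch1", "ch2")
  cl0 <- form_clusters(stat, p, neighbours = ng0)
  expect_length(cl0, 2)
  # same with neighbouring channels: 1 cluster
  cl1 <- form_clusters(stat, p, neighbours = ng)
  expect_length(cl1, 1)
  expect_equal(cl1[[1]]$cluster_stat, 8)
  # a 3x3 freq-time block on one channel is one cluster of size 9
  stat2 <- array(0, c(2, 3, 3)); p2 <- array(1, c(2, 3, 3))
  stat2[1, , ] <- 3; p2[1, , ] <- 0.01
  dimnames(stat2)[[1]] <- dimnames(p2)[[1]] <- c("ch1", "ch2")
  cl2 <- form_clusters(stat2, p2, neighbours = ng0)
  expect_length(cl2, 1)
  expect_equal(nrow(cl2[[1]]$members), 9)
  # no suprathreshold voxels: empty list
  expect_length(form_clusters(stat2, array(1, c(2, 3, 3)),
                              neighbours = ng), 0)
  # opposite polarities never merge
  stat3 <- array(c(4, -4), c(2, 1, 1)); p3 <- array(0.01, c(2, 1, 1))
  dimnames(stat3)[[1]] <- dimnames(p3)[[1]] <- c("ch1", "ch2")
  cl3 <- form_clusters(stat3, p3, neighbours = ng)
  expect_length(cl3, 2)
  expect_setequal(vapply(cl3, `[[`, character(1), "polarity"),
                  c("positive", "negative"))
})

test_that("a strong localized shift is found as a significant positive cluster", {
  set.seed(7)
  dims <- c(2, 4, 5)
  ga <- array(rnorm(8 * prod(dims)), c(8, dims))
  gb <- array(rnorm(8 * prod(dims)), c(8, dims))
  ga[, 1, 2:3, 2:4] <- ga[, 1, 2:3, 2:4] + 3
  dimnames(ga)[[2]] <- dimnames(gb)[[2]] <- c("ch1", "ch2")
  pt <- permutation_test(ga, gb, "independent_t", 1000,
                         neighbours = two_channel_graph(), seed = 3)
  sig <- Filter(function(cl) cl$significant && cl$polarity == "positive",
                pt$clusters)
  expect_gte(length(sig), 1)
  big <- sig[[which.max(vapply(sig, `[[`, numeric(1), "cluster_stat"))]]
  # the injected voxels are inside the winning cluster
  inj <- expand.grid(channel = 1, freq = 2:3, time = 2:4)
  got <- big$members[, c("channel", "freq", "time")]
  expect_true(all(apply(inj, 1, function(v)
    any(got$channel == v[1] & got$freq == v[2] & got$time == v[3]))))
  # p floors at 1/(R+1)
  expect_gte(min(vapply(pt$clusters, `[[`, numeric(1), "p_value")),
             1 / 1001)
})

test_that("permutation results are reproducible and monotone in effect size", {
  set.seed(15)
  dims <- c(2, 3, 3)
  base_a <- array(rnorm(6 * prod(dims)), c(6, dims))
  gb <- array(rnorm(6 * prod(dims)), c(6, dims))
  dimnames(base_a)[[2]] <- dimnames(gb)[[2]] <- c("ch1", "ch2")
  ng <- two_channel_graph()
  p1 <- permutation_test(base_a, gb, "independent_t", 300, neighbours = ng,
                         seed = 5)
  p2 <- permutation_test(base_a, gb, "independent_t", 300, neighbours = ng,
                         seed = 5)
  expect_identical(p1$null_max_pos, p2$null_max_pos)
  expect_identical(vapply(p1$clusters, `[[`, numeric(1), "p_value"),
                   vapply(p2$clusters, `[[`, numeric(1), "p_value"))
  # on fixed noise, growing the injected effect never shrinks the max cluster
  max_stat <- vapply(c(1, 2, 4), function(eff) {
    ga <- base_a
    ga[, 1, 2, 2] <- ga[, 1, 2, 2] + eff
    st <- samplewise_stat(ga, gb, "independent_t")
    cl <- form_clusters(st$stat, st$p, neighbours = ng, axes = st$axes)
    if (length(cl) == 0) 0 else
      max(vapply(cl, `[[`, numeric(1), "cluster_stat"))
  }, numeric(1))
  expect_true(all(diff(max_stat) >= 0))
})

test_that("paired and F variants run end to end on small volumes", {
  set.seed(20)
  dims <- c(2, 3, 1)
  ga <- array(rnorm(6 * prod(dims)), c(6, dims))
  gb <- array(rnorm(6 * prod(dims)), c(6, dims))
  gb[, 1, , ] <- gb[, 1, , ] - 1.5
  dimnames(ga)[[2]] <- dimnames(gb)[[2]] <- c("ch1", "ch2")
  ng <- two_channel_graph()
  pp <- permutation_test(ga, gb, "paired_t", 400, neighbours = ng, seed = 2)
  expect_s3_class(pp, "cluster_test")
  expect_true(all(vapply(pp$clusters, `[[`, numeric(1), "p_value") > 0))
  gc <- array(rnorm(5 * prod(dims), 2), c(5, dims))
  dimnames(gc)[[2]] <- c("ch1", "ch2")
  pf <- permutation_test(groups = list(ga, gb, gc), kind = "F",
                         n_randomizations = 400, neighbours = ng, seed = 2)
  expect_true(all(vapply(pf$clusters, `[[`, character(1), "polarity") ==
                    "single_sided"))
  expect_gte(length(Filter(function(cl) cl$significant, pf$clusters)), 1)
})

test_that("power spectra are treated as one-time-bin volumes", {
  set.seed(31)
  mk_spec <- function(shift) {
    pw <- matrix(rnorm(2 * 10, shift), 2, 10)
    structure(list(power = pw, freqs = 1:10,
                   channel_labels = c("ch1", "ch2"),
                   n_epochs_averaged = 1, method = "fixture"),
              class = "power_spectrum")
  }
  ga <- lapply(rep(2, 6), mk_spec)
  gb <- lapply(rep(0, 6), mk_spec)
  pt <- permutation_test(ga, gb, "independent_t", 300,
                         neighbours = two_channel_graph(), seed = 1)
  expect_gte(length(pt$clusters), 1)
})
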