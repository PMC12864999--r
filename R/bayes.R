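#' JZS (Cauchy-prior) Bayes factor for a two-sample comparison
#'
#' Default Bayesian t-test: the Bayes factor BF10 compares H1, under which
#' the standardized effect size delta follows a Cauchy(0, r) prior (medium
#' width r = sqrt(2)/2 by default), against the point null delta = 0. From
#' the group summaries a pooled-variance two-sample t statistic is formed and
#' the marginal likelihood under the prior is evaluated by adaptive numerical
#' integration of the noncentral-t likelihood; one-sided variants truncate
#' the prior to the predicted half-line (doubling its density there). At
#' t = 0 the one-sided and two-sided Bayes factors coincide (prior symmetry).
#'
#' @param mean1,sd1,n1 summary statistics of the first group.
#' @param mean2,sd2,n2 summary statistics of the second group.
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @param sidedness `"two_sided"`, `"one_sided_greater"` (delta > 0, i.e.
#'   group 1 larger) or `"one_sided_less"`.
#' @return object of class `bf_result`: list with `bf10`, `t_stat`, `df`,
#'   `n1`, `n2`, `prior_scale`, `sidedness`.
#' @export
jzs_bf_two_sample <- function(mean1, sd1, n1, mean2, sd2, n2,
                              r = sqrt(2) / 2,
                              sidedness = c("two_sided", "one_sided_greater",
                                            "one_sided_less")) {
  sidedness <- match.arg(sidedness)
  vals <- c(mean1, sd1, n1, mean2, sd2, n2, r)
  if (!all(is.finite(vals))) stop("non-finite inputs")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t_stat <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  bf <- jzs_bf_from_t(t_stat, n1, n2, r, sidedness)
  structure(list(bf10 = bf, t_stat = t_stat, df = df, n1 = n1, n2 = n2,
                 prior_scale = r, sidedness = sidedness),
            class = "bf_result")
}

#' @rdname jzs_bf_two_sample
#' @param x,y raw observation vectors; delegates to the summary-statistic
#'   entry point.
#' @export
jzs_bf_raw <- function(x, y, r = sqrt(2) / 2,
                       sidedness = c("two_sided", "one_sided_greater",
                                     "one_sided_less")) {
  jzs_bf_two_sample(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                    r = r, sidedness = match.arg(sidedness))
}

#' @rdname jzs_bf_two_sample
#' @param t_stat pooled-variance two-sample t statistic.
#' @export
jzs_bf_from_t <- function(t_stat, n1, n2, r = sqrt(2) / 2,
                          sidedness = "two_sided") {
  df <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  lik <- function(delta)
    suppressWarnings(dt(t_stat, df, ncp = delta * sqrt(neff)))
  f0 <- dt(t_stat, df)
  # substituting delta = r tan(u) maps the Cauchy prior to Uniform(-pi/2,
  # pi/2): the integrand becomes bounded on a finite interval
  g <- function(u) lik(r * tan(u)) / pi
  num <- switch(sidedness,
    two_sided = quad_or_error(g, -pi / 2, pi / 2),
    one_sided_greater = 2 * quad_or_error(g, 0, pi / 2),
    one_sided_less = 2 * quad_or_error(g, -pi / 2, 0),
    stop("unknown sidedness"))
  num / f0
}

quad_or_error <- function(f, lower, upper) {
  # the absolute floor lets near-zero one-sided integrals converge; it sits
  # orders of magnitude below any Bayes-factor numerator of interest
  res <- tryCatch(integrate(f, lower, upper, rel.tol = 1e-9,
                            abs.tol = 1e-14, subdivisions = 1000L),
                  error = function(e) e)
  if (inherits(res, "error"))
    res <- tryCatch(integrate(f, lower, upper, rel.tol = 1e-7,
                              abs.tol = 1e-12, subdivisions = 1000L),
                    error = function(e) e)
  if (inherits(res, "error"))
    stop("Bayes factor integration failed: ", conditionMessage(res))
  if (res$message != "OK")
    stop("Bayes factor integration did not converge: ", res$message)
  res$value
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("JZS Bayes factor (r = %.4f, %s): BF10 = %.4f (t = %.3f, n = %d/%d)\n",
              x$prior_scale, x$sidedness, x$bf10, x$t_stat, x$n1, x$n2))
  invisible(x)
}

#' Sequential open-ended design monitor
#'
#' Replays the sequential Bayesian design: testing starts once every group
#' has `k_start` (15) usable data sets and is repeated each time k grows by
#' one; data collection stops at the first look where the Bayes factor shows
#' moderate evidence for either hypothesis (BF10 >= 3 or <= 1/3) or when the
#' group size cap `k_max` (35) is reached.
#'
#' @param looks data.frame with one row per look, ordered by `k`, columns
#'   `k`, `mean1`, `sd1`, `mean2`, `sd2` (group summaries computed from the
#'   first k participants of each group); optionally `n1`, `n2` (default k).
#' @param thresholds length-2 numeric `c(upper, lower)` (default `c(3, 1/3)`).
#' @param k_start first tested group size (default 15).
#' @param k_max group size cap (default 35).
#' @param r Cauchy prior scale.
#' @param sidedness passed to [jzs_bf_two_sample()].
#' @return object of class `sequential_state`: list with `k_trace`,
#'   `bf_trace`, `decision` (`accept_H1`, `accept_H0`, `max_n_reached`,
#'   `continuing`), `k_stop`, `thresholds`.
#' @export
sequential_monitor <- function(looks, thresholds = c(3, 1 / 3),
                               k_start = 15, k_max = 35,
                               r = sqrt(2) / 2, sidedness = "two_sided") {
  stopifnot(is.data.frame(looks), all(c("k", "mean1", "sd1", "mean2", "sd2")
                                      %in% names(looks)))
  looks <- looks[looks$k >= k_start & looks$k <= k_max, , drop = FALSE]
  if (nrow(looks) == 0) stop("no looks between k_start and k_max")
  if (any(diff(looks$k) != 1) || looks$k[1] != k_start)
    stop("k trace must be contiguous from k_start")
  n1 <- if ("n1" %in% names(looks)) looks$n1 else looks$k
  n2 <- if ("n2" %in% names(looks)) looks$n2 else looks$k
  bf <- numeric(nrow(looks))
  decision <- "continuing"
  k_stop <- NA_integer_
  for (i in seq_len(nrow(looks))) {
    bf[i] <- jzs_bf_two_sample(looks$mean1[i], looks$sd1[i], n1[i],
                               looks$mean2[i], looks$sd2[i], n2[i],
                               r = r, sidedness = sidedness)$bf10
    if (bf[i] >= thresholds[1]) {
      decision <- "accept_H1"; k_stop <- looks$k[i]; break
    }
    if (bf[i] <= thresholds[2]) {
      decision <- "accept_H0"; k_stop <- looks$k[i]; break
    }
    if (looks$k[i] == k_max) {
      decision <- "max_n_reached"; k_stop <- k_max; break
    }
  }
  n_done <- if (is.na(k_stop)) nrow(looks) else which(looks$k == k_stop)
  structure(list(k_trace = looks$k[seq_len(n_done)],
                 bf_trace = bf[seq_len(n_done)],
                 decision = decision, k_stop = k_stop,
                 thresholds = thresholds, k_start = k_start, k_max = k_max,
                 sidedness = sidedness),
            class = "sequential_state")
}

#' @export
print.sequential_state <- function(x, ...) {
  cat(sprintf("Sequential design: %d look(s), k = %d..%d, decision = %s%s\n",
              length(x$k_trace), min(x$k_trace), max(x$k_trace), x$decision,
              if (!is.na(x$k_stop)) sprintf(" at k = %d (BF10 = %.3f)",
                                            x$k_stop,
                                            x$bf_trace[length(x$bf_trace)])
              else ""))
  invisible(x)
}

#' Write a sequential trace as TSV
#' @param state a `sequential_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequential_tsv <- function(state, path) {
  df <- data.frame(k = state$k_trace, bf10 = state$bf_trace,
                   decision = c(rep("continuing",
                                    length(state$k_trace) - 1),
                                state$decision))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
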