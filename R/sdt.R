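#' Boundary-corrected response rate
#'
#' Guards the z-transform at extreme rates: the log-linear correction
#' `(count + 0.5) / (n + 1)` is applied only when the count is 0 or n;
#' otherwise the raw proportion `count / n` is returned.
#'
#' @param count number of successes (0..n).
#' @param n denominator (> 0).
#' @return corrected rate in (0, 1).
#' @export
rate_correction <- function(count, n) {
  if (any(n == 0)) stop("zero denominator")
  if (any(count < 0 | count > n)) stop("count must be in 0..n")
  ifelse(count == 0 | count == n, (count + 0.5) / (n + 1), count / n)
}

#' Signal-detection scoring of a recognition table
#'
#' Extracts the four recognition outcomes (hits: old pairs remembered;
#' misses: old pairs not remembered; correct rejections: recombined pairs
#' rejected; false alarms: recombined pairs endorsed as old), computes hit
#' and false-alarm rates over the valid-trial denominators (missed-response
#' trials, i.e. no response within the 3 s window, are excluded), and the
#' sensitivity index d' = z(hit rate) - z(false-alarm rate). Participants
#' whose false-alarm rate exceeds 25% are marked excluded.
#'
#' @param trials data.frame with columns `status` (`"old"`/`"new"`) and
#'   `response` (`"old"`/`"new"`/`NA` for missed); an optional `rt_ms` column
#'   marks responses slower than `max_rt_ms` as missed.
#' @param fa_exclusion_threshold false-alarm-rate exclusion cutoff
#'   (default 0.25).
#' @param max_rt_ms response window in ms (default 3000).
#' @return object of class `sdt_summary`: one-row data.frame with counts
#'   (`hits`, `misses`, `crs`, `fas`, `missed`), `hit_rate`, `fa_rate`,
#'   `dprime` and `excluded`.
#' @export
score_recognition <- function(trials, fa_exclusion_threshold = 0.25,
                              max_rt_ms = 3000) {
  stopifnot(all(c("status", "response") %in% names(trials)))
  resp <- trials$response
  if ("rt_ms" %in% names(trials))
    resp[!is.na(trials$rt_ms) & trials$rt_ms > max_rt_ms] <- NA
  missed <- is.na(resp)
  old <- trials$status == "old"
  valid_old <- sum(old & !missed)
  valid_new <- sum(!old & !missed)
  if (valid_old == 0 || valid_new == 0)
    stop("no valid old or new trials to score")
  hits <- sum(old & !missed & resp == "old")
  fas <- sum(!old & !missed & resp == "old")
  hit_rate <- rate_correction(hits, valid_old)
  fa_rate <- rate_correction(fas, valid_new)
  out <- data.frame(
    hits = hits, misses = valid_old - hits, crs = valid_new - fas, fas = fas,
    missed = sum(missed), hit_rate = hit_rate, fa_rate = fa_rate,
    dprime = qnorm(hit_rate) - qnorm(fa_rate),
    excluded = fa_rate > fa_exclusion_threshold)
  class(out) <- c("sdt_summary", "data.frame")
  out
}

#' Score a whole cohort of recognition tables
#'
#' @param behaviors named list, each element a list with `trials` (as from
#'   [simulate_behavior()]) or directly a trial data.frame.
#' @param groups optional group ids per participant.
#' @return data.frame, one row per participant, with `participant`, `group`
#'   and the [score_recognition()] columns.
#' @export
score_cohort <- function(behaviors, groups = NA_character_) {
  rows <- lapply(seq_along(behaviors), function(i) {
    b <- behaviors[[i]]
    tr <- if (is.data.frame(b)) b else b$trials
    cbind(participant = if (is.null(names(behaviors))) i else names(behaviors)[i],
          group = if (length(groups) == 1) groups else groups[i],
          score_recognition(tr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Encoding-task accuracy (animal categorization)
#'
#' Simple proportion of correct categorization responses during encoding;
#' reported descriptively only.
#'
#' @param encoding data.frame with a logical `correct` column.
#' @return proportion correct.
#' @export
score_encoding_accuracy <- function(encoding) {
  stopifnot("correct" %in% names(encoding))
  mean(encoding$correct)
}

#' Size-matched subsample of the no-entrainment group
#'
#' The NE reference cohort is larger (k = 45) than the entrainment groups
#' (k = 35). Fifty random size-`target_k` subsamples are drawn without
#' replacement; the one whose mean sensitivity is closest to the full-sample
#' mean is retained (ties broken by first occurrence), ensuring the
#' subsample is representative of the original sample.
#'
#' @param ne_scores numeric vector of per-participant d' values.
#' @param target_k subsample size (default 35).
#' @param draws number of candidate subsamples (default 50).
#' @param seed optional integer seed.
#' @return list with `indices`, `scores`, `mean`, `full_mean`,
#'   `candidate_means` (all 50 recorded for provenance) and `chosen` (the
#'   index of the selected draw).
#' @export
ne_subsample_match <- function(ne_scores, target_k = 35, draws = 50,
                               seed = NULL) {
  if (target_k > length(ne_scores))
    stop("target_k exceeds the available sample size")
  if (!is.null(seed)) set.seed(seed)
  full_mean <- mean(ne_scores)
  cand <- lapply(seq_len(draws), function(i)
    sample.int(length(ne_scores), target_k))
  means <- vapply(cand, function(ix) mean(ne_scores[ix]), numeric(1))
  chosen <- which.min(abs(means - full_mean))
  list(indices = cand[[chosen]], scores = ne_scores[cand[[chosen]]],
       mean = means[chosen], full_mean = full_mean,
       candidate_means = means, chosen = chosen)
}
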