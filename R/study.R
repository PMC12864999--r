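#' Reported group-level behavioural summaries
#'
#' The group summary statistics of the study this pipeline replicates, used
#' as the generative targets of the cohort simulator and as inputs for
#' summary-statistic Bayes factors: sensitivity d' (mean, SD) per group, and
#' hit / false-alarm rates (percent) for the groups where they are reported.
#' Group sizes are k = 35 for the three stimulation groups and k = 45 for the
#' no-entrainment (NE) reference cohort (matched to 35 for its contrasts).
#'
#' @return data.frame with columns `group`, `measure`, `mean`, `sd`, `n`.
#' @export
study_group_summaries <- function() {
  data.frame(
    group = c("theta", "alpha", "control", "ne",
              "alpha", "control", "ne",
              "alpha", "control", "ne"),
    measure = c(rep("dprime", 4), rep("hit_rate_pct", 3), rep("fa_rate_pct", 3)),
    mean = c(1.28, 1.46, 1.18, 1.27,
             61.498, 49.792, 52.662,
             13.9, 13.0, 12.8),
    sd = c(0.55, 0.60, 0.50, 0.53,
           14.443, 15.029, 13.724,
           6.67, 5.73, 6.1),
    n = c(35, 35, 35, 45, 35, 35, 45, 35, 35, 45))
}

#' Study-level configuration
#'
#' Bundles the cohort configuration with all analysis-stage parameters. The
#' defaults equal the study's values: 0.5-40 Hz band-pass, accumulated-z
#' cutoffs 60 (jump) and 30 (muscle), 500 ms Hanning TFR at 100 ms steps over
#' 1-40 Hz, percent-change baseline -3.1 to -2.1 s, 10% / 500 ms entrainment
#' criterion in the -1.1 to -0.1 s window, 4000 randomizations with
#' cluster alpha 0.025 per tail, 25% false-alarm exclusion, Cauchy prior
#' r = sqrt(2)/2 with sequential thresholds (3, 1/3) and k from 15 to 35.
#'
#' @param cohort a [cohort_config()].
#' @param bandpass_low,bandpass_high filter band (Hz).
#' @param jump_threshold,muscle_threshold accumulated-z cutoffs.
#' @param tfr_window,tfr_step Hanning TFR parameters (s).
#' @param baseline_window percent-change baseline (s).
#' @param entrain_threshold,entrain_min_ms,entrain_window entrainment
#'   criterion parameters.
#' @param n_randomizations,alpha_sample,alpha_cluster cluster test
#'   parameters.
#' @param cluster_window time window (s) of the cluster contrasts.
#' @param fa_exclusion false-alarm-rate exclusion threshold.
#' @param prior_scale Cauchy prior r.
#' @param bf_thresholds,k_start,k_max sequential design parameters.
#' @param ica_hook function applied to each participant's epochs after
#'   artifact rejection (identity by default; slot for externally cleaned
#'   data, e.g. after independent component removal).
#' @param output_dir optional directory for report files.
#' @param seed master seed; fully determines every stochastic stage.
#' @return list of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         bandpass_low = 0.5, bandpass_high = 40,
                         jump_threshold = 60, muscle_threshold = 30,
                         tfr_window = 0.5, tfr_step = 0.1,
                         baseline_window = c(-3.1, -2.1),
                         entrain_threshold = 10, entrain_min_ms = 500,
                         entrain_window = c(-1.1, -0.1),
                         n_randomizations = 4000, alpha_sample = 0.05,
                         alpha_cluster = 0.025,
                         cluster_window = c(-1.1, -0.1),
                         fa_exclusion = 0.25,
                         prior_scale = sqrt(2) / 2,
                         bf_thresholds = c(3, 1 / 3),
                         k_start = 15, k_max = 35,
                         ica_hook = identity,
                         output_dir = NULL,
                         seed = cohort$seed) {
  structure(as.list(environment()), class = "study_config")
}

#' Run the full study replica
#'
#' Executes, under one master seed, every stage of the pipeline on a
#' synthetic cohort: simulation, band-pass filtering, accumulated-z artifact
#' rejection, the (pass-through) component-removal hook, common-average
#' re-referencing, Hanning TFR with percent-change baselining, entrainment
#' screening with exclusion of unsuccessfully entrained participants,
#' cluster-based permutation contrasts of the entrainment groups against the
#' control group in the late entrainment window, signal-detection scoring
#' with false-alarm exclusions (applied after the entrainment screening, in
#' the study's order), NE subsample matching where applicable, and the JZS
#' Bayes factor table for the behavioural contrasts.
#'
#' @param config a [study_config()].
#' @return list of class `study_report`: `entrainment` (assessment table),
#'   `exclusions`, `cluster_tests`, `sdt` (per-participant table),
#'   `bf_table`, `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cc <- config$cohort
  set.seed(config$seed)
  stage <- "simulate"
  report <- list()
  on.exit(if (!is.null(report$failed_stage))
    message("run_study aborted in stage: ", report$failed_stage), add = TRUE)
  result <- tryCatch({
    participants <- list()
    for (g in cc$groups) {
      for (i in seq_len(cc$k_per_group)) {
        id <- sprintf("%s_%02d", g, i)
        participants[[id]] <- simulate_participant(
          cc, g, id = id, seed = sample.int(.Machine$integer.max, 1))
      }
    }

    stage <- "preprocess"
    neigh <- channel_neighbours()
    for (id in names(participants)) {
      ep <- participants[[id]]$epochs
      ep <- bandpass(ep, config$bandpass_low, config$bandpass_high)
      ep <- zscore_artifact_reject(ep, config$jump_threshold,
                                   config$muscle_threshold)
      ep <- config$ica_hook(ep)
      ep <- common_average_reference(ep)
      participants[[id]]$epochs <- ep
    }

    stage <- "tfr"
    tfrs <- lapply(participants, function(p) {
      tfr <- tfr_hanning(p$epochs, config$tfr_window, config$tfr_step)
      baseline_percent_change(tfr, config$baseline_window)
    })

    stage <- "entrainment_screening"
    groups_of <- vapply(participants, `[[`, character(1), "group")
    assessments <- list()
    for (id in names(participants)) {
      g <- groups_of[id]
      if (g %in% c("theta", "alpha"))
        assessments[[id]] <- assess_entrainment(
          tfrs[[id]], group_frequency(g), config$entrain_threshold,
          config$entrain_min_ms, config$entrain_window)
    }
    ent_tab <- if (length(assessments))
      entrainment_table(assessments, groups_of[names(assessments)])
    else data.frame(participant = character(0), passed = logical(0))
    excl_entrain <- ent_tab$participant[!ent_tab$passed]

    stage <- "cluster_statistics"
    in_window <- function(tfr) {
      ti <- tfr$times >= config$cluster_window[1] - 1e-9 &
        tfr$times <= config$cluster_window[2] + 1e-9
      tfr$power <- tfr$power[, , ti, drop = FALSE]
      tfr$times <- tfr$times[ti]
      tfr
    }
    keep_eeg <- setdiff(names(participants), excl_entrain)
    cluster_tests <- list()
    for (g in intersect(c("theta", "alpha"), cc$groups)) {
      if (!("control" %in% cc$groups)) break
      ga <- lapply(keep_eeg[groups_of[keep_eeg] == g],
                   function(id) in_window(tfrs[[id]]))
      gb <- lapply(keep_eeg[groups_of[keep_eeg] == "control"],
                   function(id) in_window(tfrs[[id]]))
      if (length(ga) >= 2 && length(gb) >= 2)
        cluster_tests[[paste0(g, "_vs_control")]] <- permutation_test(
          ga, gb, "independent_t", config$n_randomizations,
          config$alpha_sample, config$alpha_cluster, neighbours = neigh)
    }

    stage <- "behaviour"
    sdt <- score_cohort(lapply(participants, `[[`, "behavior"), groups_of)
    sdt$true_dprime <- vapply(participants, function(p)
      p$truth$true_dprime, numeric(1))
    sdt$excluded_entrainment <- sdt$participant %in% excl_entrain
    sdt$excluded_fa <- sdt$excluded
    analyzed <- sdt[!sdt$excluded_entrainment & !sdt$excluded_fa, ]

    stage <- "bayes_inference"
    gsum <- function(g) {
      x <- analyzed$dprime[analyzed$group == g]
      c(mean = mean(x), sd = sd(x), n = length(x))
    }
    contrasts <- list(
      list(id = "H2a_theta_gt_control", a = "theta", b = "control",
           sidedness = "one_sided_greater"),
      list(id = "H2b_alpha_gt_control", a = "alpha", b = "control",
           sidedness = "one_sided_greater"),
      list(id = "H2c_theta_vs_alpha", a = "theta", b = "alpha",
           sidedness = "two_sided"))
    if ("ne" %in% cc$groups) {
      ne_scores <- analyzed$dprime[analyzed$group == "ne"]
      k_target <- min(config$k_max,
                      min(table(analyzed$group[analyzed$group != "ne"])))
      ne_match <- if (length(ne_scores) > k_target)
        ne_subsample_match(ne_scores, k_target) else
        list(scores = ne_scores, candidate_means = mean(ne_scores))
      contrasts <- c(contrasts, list(
        list(id = "H3_theta_gt_ne", a = "theta", b = "__ne_matched",
             sidedness = "one_sided_greater"),
        list(id = "H3_alpha_gt_ne", a = "alpha", b = "__ne_matched",
             sidedness = "one_sided_greater")))
    }
    bf_rows <- lapply(contrasts, function(ct) {
      sa <- gsum(ct$a)
      sb <- if (ct$b == "__ne_matched")
        c(mean = mean(ne_match$scores), sd = sd(ne_match$scores),
          n = length(ne_match$scores)) else gsum(ct$b)
      if (sa["n"] < 2 || sb["n"] < 2) return(NULL)
      bf <- jzs_bf_two_sample(sa["mean"], sa["sd"], sa["n"],
                              sb["mean"], sb["sd"], sb["n"],
                              r = config$prior_scale, sidedness = ct$sidedness)
      data.frame(contrast = ct$id, sidedness = ct$sidedness,
                 mean1 = sa["mean"], sd1 = sa["sd"], n1 = sa["n"],
                 mean2 = sb["mean"], sd2 = sb["sd"], n2 = sb["n"],
                 t = bf$t_stat, bf10 = bf$bf10)
    })
    bf_table <- do.call(rbind, bf_rows)
    rownames(bf_table) <- NULL

    excl_e <- sdt$excluded_entrainment & !sdt$excluded_fa
    excl_f <- sdt$excluded_fa & !sdt$excluded_entrainment
    excl_b <- sdt$excluded_fa & sdt$excluded_entrainment
    report <- structure(list(
      entrainment = ent_tab,
      exclusions = data.frame(
        simulated = nrow(sdt), excluded_entrainment = sum(excl_e),
        excluded_fa = sum(excl_f), excluded_both = sum(excl_b),
        analyzed = nrow(analyzed)),
      cluster_tests = cluster_tests,
      sdt = sdt,
      bf_table = bf_table,
      provenance = list(seed = config$seed,
                        k_per_group = cc$k_per_group,
                        groups = cc$groups,
                        n_randomizations = config$n_randomizations,
                        package_version =
                          as.character(utils::packageVersion("entrainr")))
    ), class = "study_report")

    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      write.table(ent_tab, file.path(config$output_dir, "entrainment.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(sdt, file.path(config$output_dir, "sdt.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(bf_table, file.path(config$output_dir, "bayes_factors.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      for (nm in names(cluster_tests))
        write_cluster_results(cluster_tests[[nm]],
                              tsv_path = file.path(config$output_dir,
                                                   paste0("cluster_", nm, ".tsv")))
      jsonlite::write_json(report$provenance,
                           file.path(config$output_dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    report
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n")
  print(x$exclusions)
  if (!is.null(x$bf_table)) print(x$bf_table[, c("contrast", "t", "bf10")])
  invisible(x)
}

#' Read / write a continuous recording (internal serialization)
#'
#' The simulator's recordings are persisted with R's native serialization;
#' a round trip is bit-identical. An `eeg_recording` carries channels,
#' sampling rate and the event table.
#'
#' @param recording an `eeg_recording`.
#' @param path file path.
#' @return `read_recording` returns the `eeg_recording`; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- readRDS(path)
  if (!inherits(rec, "eeg_recording"))
    stop("file does not contain an eeg_recording")
  if (is.null(rec$events) || nrow(rec$events) == 0)
    stop("recording has no event markers")
  rec
}

#' Write a behaviour table as TSV
#'
#' Schema: `participant`, `group`, `run`, `trial`, `status`, `response`,
#' `rt_ms` (the same schema is accepted back by [score_recognition()]).
#'
#' @param behavior result of [simulate_behavior()] (or its `trials` field).
#' @param path output path.
#' @param participant,group identifier columns.
#' @return `path`, invisibly.
#' @export
write_behavior_tsv <- function(behavior, path, participant = 1L,
                               group = NA_character_) {
  tr <- if (is.data.frame(behavior)) behavior else behavior$trials
  df <- cbind(participant = participant, group = group,
              tr[, c("run", "trial", "status", "response", "rt_ms")])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
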