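#!/usr/bin/env Rscript
# Preprocessing: 0.5-40 Hz zero-phase band-pass, accumulated z-score
# artifact rejection (z = 60 jumps, z = 30 muscle) and common-average
# re-referencing of the simulated cohort. Compares the rejection flags with
# the simulator's injection log.

suppressPackageStartupMessages(library(entrainr))
cohort <- readRDS("results/cohort/cohort.rds")
dir.create("results/preprocessed", recursive = TRUE, showWarnings = FALSE)

flags <- truth_flags <- list()
for (id in names(cohort)) {
  ep <- cohort[[id]]$epochs
  ep <- bandpass(ep, 0.5, 40)
  ep <- zscore_artifact_reject(ep, jump_threshold = 60,
                               muscle_threshold = 30)
  ep <- common_average_reference(ep)
  cohort[[id]]$epochs <- ep
  write_rejection_log(ep, sprintf("results/preprocessed/rejections_%s.tsv", id))
  flags[[id]] <- ep$rejected$trial
  truth_flags[[id]] <- cohort[[id]]$truth$artifact_trials
}
saveRDS(cohort, "results/preprocessed/cohort.rds")

detected <- unlist(lapply(names(cohort), function(id)
  truth_flags[[id]] %in% flags[[id]]))
false_flags <- unlist(lapply(names(cohort), function(id)
  setdiff(flags[[id]], truth_flags[[id]])))
n_clean <- sum(vapply(cohort, function(p) n_trials(p$epochs), integer(1))) -
  length(unlist(truth_flags))
cat(sprintf("Artifact rejection: %d/%d injected trials flagged (%.0f%%), %d false flags on %d clean trials (%.1f%%)\n",
            sum(detected), length(detected), 100 * mean(detected),
            length(false_flags), n_clean, 100 * length(false_flags) / n_clean))
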