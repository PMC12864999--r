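# entrainr

An R package and analysis workflow replicating the computational apparatus
of a pre-stimulus visual sensory-entrainment EEG study of crossmodal
associative memory.

## The problem

Pre-stimulus theta (3–7 Hz) and alpha (8–12 Hz) power predict whether an
upcoming image–sound pair will later be remembered. To test whether that
link is causal, a luminance-modulated image is shown for 2 s before each
encoding trial, driving occipital oscillations at 5 Hz (theta group), 9 Hz
(alpha group), or with an arhythmic chained-cycle waveform (control); a
no-entrainment (NE) cohort saw a static fixation cross. Two analysis chains
follow:

* **EEG**: 0.5–40 Hz band-pass, epoching (−3.4…+2.5 s), accumulated z-score
  artifact rejection (cutoffs z = 60 jump / z = 30 muscle), common-average
  reference, 500 ms-Hanning time–frequency power (1–40 Hz, 100 ms steps),
  percent change from the −3.1…−2.1 s baseline, a 10%/500 ms entrainment
  success criterion in the late window (−1.1…−0.1 s), and cluster-based
  permutation contrasts (sample-level t, 4000 randomizations, corrected
  p < .025 per tail) across channel × frequency × time.
* **Behaviour**: equal-variance signal detection on old/new recognition,
  d′ = z(hit rate) − z(false-alarm rate), exclusion at false-alarm rate
  > 25%, NE subsample matching (best of 50 draws), and JZS Bayes factors
  (Cauchy prior, r = √2/2) with a sequential design (test from k = 15,
  stop at BF₁₀ ≥ 3 or ≤ 1/3 or k = 35).

The original recordings are an external deposit, so the package ships a
synthetic cohort generator that emulates the study's data structure
(64-channel 500 Hz EEG with an occipitally peaked entrained component over
a 1/f background, SDT-generated recognition tables using the reported
group-level d′ distributions). Every stage is exercised and calibrated on
that generator.

## Layout

* `R/` — the package: waveforms, cohort simulation, preprocessing,
  time–frequency, entrainment metrics, cluster permutation (Rcpp core in
  `src/`), SDT scoring, Bayes factors, and the `run_study()` orchestrator.
* `analysis/01…06_*.R` — numbered drivers that walk the full study replica
  on a demonstration cohort and write tables under `results/`.
* `tests/testthat/` — unit, property and acceptance tests.
* `scripts/acceptance.R` — recomputes the headline quantities (see below).
* `vignettes/entrainment-pipeline.Rmd` — the methods vignette: models,
  assumptions, parameter choices, limitations.

## Worked example

Bayes factors from the reported group summaries (k = 35 per group):

```r
library(entrainr)
gs <- study_group_summaries()
a <- subset(gs, group == "alpha"   & measure == "dprime")
c <- subset(gs, group == "control" & measure == "dprime")
jzs_bf_two_sample(a$mean, a$sd, 35, c$mean, c$sd, 35,
                  sidedness = "one_sided_greater")
#> JZS Bayes factor (r = 0.7071, one_sided_greater): BF10 = 3.1868 (t = 2.121, n = 35/35)
```

Moderate evidence that alpha entrainment improves recognition sensitivity
relative to the arhythmic control (the reported value is 3.29; the
difference is rounding of the two-decimal printed summaries).

A miniature study end to end — simulate, preprocess, screen entrainment,
cluster-test, score and infer — in one call:

```r
cfg <- study_config(
  cohort = cohort_config(groups = c("theta", "alpha", "control"),
                         k_per_group = 4, runs = 1,
                         encoding_trials_per_run = 8,
                         channel_labels = c("O1","O2","Oz","POz","Pz",
                                            "P3","P4","PO3","PO4","Cz",
                                            "HEOGL"),
                         seed = 77),
  n_randomizations = 200)
run_study(cfg)
#> Study report
#>   simulated excluded_entrainment excluded_fa excluded_both analyzed
#> 1        12                    2           1             0        9
```

The exclusion bookkeeping mirrors the study's participant flow: entrainment
screening first, then the false-alarm rule, overlap tracked separately.

The demonstration workflow (8 participants per group, 24 trials) is run by
the numbered scripts:

```sh
Rscript analysis/01_stimulus_waveforms.R   # waveforms + duration stats
Rscript analysis/02_simulate_cohort.R      # synthetic cohort
Rscript analysis/03_preprocess.R           # filtering, rejection, CAR
Rscript analysis/04_entrainment_validation.R
Rscript analysis/05_cluster_statistics.R
Rscript analysis/06_behavioral_inference.R
```

Representative output: `03` reports `42/43 injected trials flagged (98%),
0 false flags on 725 clean trials`; `04` reports `Entrainment screening:
16/16 passed`; `05` finds significant positive clusters in the stimulated
bands (and negative clusters where the arhythmic drive elevates control
power); `06` prints the simulated-cohort and reference Bayes factors and a
sequential-design replay.

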