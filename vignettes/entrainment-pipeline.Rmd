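---
title: "Methods: a pre-stimulus sensory-entrainment EEG pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a pre-stimulus sensory-entrainment EEG pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainr)
```

# The experiment this package replicates

`entrainr` implements, end to end, the computational apparatus of a visual
sensory-entrainment study of crossmodal associative memory. Participants
encode image-sound pairs; immediately before each pair, a 2 s luminance-
modulated image attempts to entrain occipital oscillations at 5 Hz (theta
group), 9 Hz (alpha group), or with an arhythmic waveform (control). A fourth
cohort (NE) saw only a static fixation cross. The questions are whether the
stimulation raises narrow-band pre-stimulus power (validated with
time-frequency analysis and cluster-based permutation statistics) and whether
it improves later old/new recognition (quantified with the sensitivity index
d' and JZS Bayes factors under a sequential design).

Because the original raw data are an external deposit, every stage runs
against a synthetic cohort generator whose structure mirrors the study's
data. The generator is first-class, tested code: the operating
characteristics of the statistical machinery (type-I calibration, criterion
sensitivity/specificity, parameter recovery) are established on it.

# Stimulus waveforms

Rhythmic stimulation is a raised cosine, $L(t) = (1 - \cos 2\pi f t)/2$. The
description "sinusoidal luminance that starts and ends at zero (image not
visible)" admits only this mapping: a signed sine would be negative half the
time. The waveform is sampled on the closed frame grid $t_k = k/240$ s,
$k = 0..480$ for 2 s — the only uniform grid with the exact 4.1667 ms frame
interval on which both the first and last frame are exactly zero for an
integer cycle count.

The arhythmic control chains complete single raised-cosine cycles with
frequencies drawn uniformly from the integers 13–24 Hz excluding 15, 18 and
20 Hz (harmonics of 5 and 9 Hz). Cycles are appended while the running total
does not exceed the 2 s target (greedy stop-before-overflow). Neither the
integer-valued pool nor the stopping rule is uniquely determined by the
study's description; both were fixed once because they reproduce the
reported duration statistics (simulated M ≈ 1.971 s, SD ≈ 0.018 s against
reported M = 1.976, SD = 0.022) and are the simplest rules consistent with
"single cycles pulled randomly" and "duration comparable to 2 s". The
post-stimulation gap is half a stimulation cycle (100 ms at 5 Hz, 56 ms at
9 Hz, rounded to integer ms) and fixed at 50 ms for the control.

# The synthetic cohort generator

`simulate_eeg_trial()` builds one −3.4…+2.5 s epoch at 500 Hz as a sum of:

* **1/f^χ background** (default χ = 1, SD 10 µV): spectrally shaped white
  noise, the canonical EEG broadband model.
* **Ongoing ~10 Hz alpha** (default 3 µV) with random phase per trial,
  posterior-weighted.
* **The entrained component**: a sinusoid at the group frequency during the
  stimulation interval (−2.1 s to the group's gap), with an exponential
  amplitude ramp (default time constant 0.3 s) toward a plateau — the
  stimulation literature consistently describes entrainment as developing
  over time — and a spatial profile peaking at O1/O2/Oz. The control group
  receives the mean-removed chained-cycle luminance drive instead, which
  reproduces the broadband beta-range elevation such stimulation produces.
  The NE group has no driven component.
* **A damped evoked transient** after stimulus onset.

The default entrained amplitude (6 µV against 10 µV broadband noise) makes
entrainment robust at the participant level: the 10%/500 ms criterion passes
essentially always for stimulated participants and rarely (< 10%) for
unstimulated ones. The generator deliberately does **not** model volume
conduction, a realistic head geometry, or the distinction between true
phase-aligned entrainment and a superposition of evoked responses — in scalp
EEG these are not separable, and the study's own analysis treats them as one
additive power change. Passing tests therefore validate the *statistical
machinery* under a faithful data structure, not biophysical realism.

Behaviour follows an equal-variance signal-detection model: each
participant's true d' is drawn from the group's Normal(M, SD) truncated at
zero, with the four reported group distributions (theta 1.28/0.55, alpha
1.46/0.60, control 1.18/0.50, NE 1.27/0.53) as defaults; old-pair
familiarity is Normal(d', 1), recombined-pair familiarity Normal(0, 1), and
the response is "old" above a criterion c. The default c = 1.1 (a
conservative bias) was chosen once because it maps the reported d' means
onto the reported hit (~50–62%) and false-alarm (~13–14%) rates;
an unbiased c = d'/2 would not. Reaction times are shifted-lognormal;
responses slower than 3 s are missed-response trials.

Artifacts are injected on demand: a step discontinuity across scalp
channels ("jump", default 500 µV), a 200 ms 30–40 Hz burst with random
per-channel gains ("muscle", default 100 µV), and a slow frontal deflection
("blink"). Jump and muscle amplitudes were set so that the rejection
pipeline at its printed cutoffs detects them reliably while clean trials
pass — the injection is plumbing for testing the detector, not a model of
artifact physiology.

# Preprocessing

Filtering is a zero-phase (forward-backward) Butterworth band-pass,
0.5–40 Hz by default; the filter family and order are visible in the code
and the band is a parameter.

Artifact rejection replicates the accumulated z-value approach: per artifact
type, a feature series per channel and trial (jump: absolute first
difference of the median-subtracted signal; muscle: band-limited Hilbert
envelope), z-transformed per channel against moments pooled over the whole
epoch set, accumulated over channels as $\sum_c z_c / \sqrt{n_{ch}}$, and
reduced to the per-trial maximum. Cutoffs default to z = 60 (jump) and
z = 30 (muscle). Two documented adaptations: (1) the usual muscle filter
targets frequencies above the 40 Hz low-pass, so the detector here uses a
30–40 Hz envelope — the high-frequency surrogate available inside the
filtered band; (2) the channel-*sum* convention (rather than a channel
average) is used because it is the convention under which cutoffs of this
magnitude are meaningful — a channel-averaged z mathematically cannot exceed
roughly the reciprocal square root of the artifact sample fraction, which at
realistic rates is ~20, below the jump cutoff. Trials flagged by both
detectors carry the jump reason. Independent-component removal is out of
scope; `study_config(ica_hook =)` accepts a function slot where externally
cleaned data can be substituted.

# Time-frequency analysis

`tfr_hanning()` computes short-time Fourier power with a fixed 500 ms
Hanning taper at 100 ms steps, 1–40 Hz in 1 Hz bins, output times
−3.1…+2.2 s; the 300 ms retained beyond the output range is used purely as
window padding. A fixed window length (not cycles-per-frequency) matches the
single stated taper. Power is scaled so a sinusoid of amplitude A yields
A²/2 at its bin. Percent-change baselining uses the −3.1…−2.1 s window
(before stimulation onset): $100 (P - B)/B$, with B the mean over baseline
times of **trial-averaged** power — trial-averaging precedes normalization,
matching the stated order ("averaged over trials … then normalized"); a
per-trial baseline would be the other defensible reading. Zero or negative
baseline power is an error naming the offending channel and frequency.

Resting spectra use DPSS (Slepian) multitapers with ±2 Hz smoothing; on 2 s
epochs this is a time-bandwidth product of 4 and 7 tapers, computed from the
standard tridiagonal eigenproblem and cached. The individual alpha/theta
frequency (IAF/ITF) is the argmax of posterior-electrode-averaged power in
8–12 / 3–7 Hz, ties broken toward the lower frequency with a warning. Two
electrode sets appear in the source analyses (a five- and a nine-electrode
posterior set); the larger nine-electrode set is the default and the set is
a parameter. A known limitation: peak-picking on a 1/f-sloped spectrum is
pulled downward by the slope (about −1 Hz for theta-range peaks at the
default simulation amplitudes); the simulator reproduces this property of
real spectra rather than hiding it.

# Entrainment criterion

Entrainment is deemed successful when the percent-change time course —
averaged over O1/O2/Oz and the stimulation band (f ± 1 Hz) — stays at or
above 10% for at least 500 ms within the late entrainment window
(−1.1…−0.1 s). With the 100 ms step this means ≥ 5 contiguous bins; a run of
m bins counts as m × 100 ms, capped at the 1000 ms window span (the 11 bin
centres otherwise nominally cover 1100 ms). The window holds the *late* half
of stimulation because entrainment builds up over time. The criterion is
evaluated on the trial-averaged time course (per-trial evaluation is not
stated in the source and is not implemented). Entrainment strength is the
maximum of the same time course.

# Cluster-based permutation statistics

Sample-level statistics (pooled-variance independent t, paired t, or one-way
F) are computed per (channel, frequency, time) voxel; voxels with
sample-level p strictly below .05 are organized into connected components
under channel-neighbourhood, ±1 frequency bin, or ±1 time bin adjacency,
separately per polarity for t. Cluster statistic = sum of member statistics;
any suprathreshold voxel can seed a cluster (no minimum size). The null
distribution redraws group labels (or flips pairs) — 4000 randomizations in
the study configuration — recording the maximum positive and minimum
negative cluster statistic per randomization; the observed data is included
in the denominator, p = (b+1)/(R+1), so p is never 0 and is floored at
1/(R+1). A cluster is significant below .025 per tail (t) or .05 (F).
Exceedance counting uses a relative tolerance of 1e−8 so that the observed
value's own replicate (reached through a different arithmetic path) counts
as a tie rather than falling on the wrong side of floating-point noise.

The channel neighbourhood comes from an idealized flat 10-20/10-10 template
generated in code (concentric rings, arc interpolation), with neighbours
defined by a distance threshold of 0.28 layout units (~nearest lateral and
row spacings); the graph is symmetric, irreflexive, leaves no scalp channel
isolated, and is serialized with results. It carries the topology of a
standard 64-channel cap, not measured positions — the original template is
a toolbox internal that is not printed.

The permutation engine's component search is compiled (Rcpp); the statistic
volumes for all randomizations are computed by blocked BLAS matrix algebra.
A `label_matrix` argument accepts an explicit enumeration of label splits,
which the tests use to check Monte-Carlo p-values against the exact
distribution over all 70 splits of a 4-vs-4 toy problem.

# Behaviour: SDT scoring and Bayes factors

d' = z(hit rate) − z(false-alarm rate), with hits/misses/correct
rejections/false alarms counted over valid-trial denominators (missed
responses excluded). Boundary rates use the log-linear correction
(count + 0.5)/(n + 1) *only* at 0 or n — the correction rule is not stated
in the source; this minimal variant leaves all interior rates untouched.
Rates pool across the three runs (per-run averaging is the alternative
reading). Participants with a false-alarm rate strictly above 25% are
excluded. The NE cohort (k = 45) is matched to k = 35 by drawing 50 random
subsamples and keeping the one whose mean d' is closest to the full-sample
mean (ties to the first; all 50 candidate means are recorded).

The JZS Bayes factor places a Cauchy(0, r = √2/2) prior on the standardized
effect and evaluates the marginal likelihood of the pooled-variance t
statistic by adaptive quadrature after the substitution δ = r·tan(u), which
maps the prior to a uniform density on a finite interval (bounded integrand,
no tail truncation). One-sided variants truncate the prior to the predicted
half-line, doubling its density (so BF⁺ + BF⁻ = 2·BF two-sided, asserted
numerically, and at t = 0 one- and two-sided agree). The summary-statistic
entry point is primary since the study reports M/SD/n; raw vectors delegate
to it. The d' contrasts use the stated sidedness (one-sided for each
entrainment group vs control, two-sided between entrainment groups). For the
hit-rate contrast the sidedness is not reported; the two-sided variant is
what brackets the reported value (the directional variant is almost exactly
its double at that t) and is the one reported, flagged as such. Bayesian
ANOVAs (one-way and mixed designs) are out of scope; the pipeline reports
descriptive summaries where the study reports ANOVA Bayes factors.

The sequential monitor replays the open-ended design: testing starts at
k = 15 per group, repeats at every added participant, and stops at BF ≥ 3,
BF ≤ 1/3, or k = 35.

# The study orchestrator

`run_study()` executes all stages under one master seed — simulation,
filtering, rejection, the ICA hook, re-referencing, TFR, entrainment
screening, cluster contrasts in the late window, SDT scoring, NE matching
and the Bayes-factor table — applying exclusions in the study's order
(entrainment screening first, then the FA rule, with the overlap tracked
separately) and writing a TSV/JSON report tree. Re-running with the same
seed reproduces the report bit-for-bit.

# Problem sizes used by tests and scripts

The packaged analyses run at desk scale, chosen once as the smallest sizes
at which each check is statistically meaningful: the type-I calibration uses
200 null cohorts of 8 subjects per group (6 trials, a 12-channel posterior
montage, 500 randomizations) — at the nominal .025 level this yields an
expected 5 significant replicates with a binomial SD of ~2.2, enough to
detect miscalibration by a factor of two; criterion sensitivity/specificity
use 25 participants of 20 trials per class; parameter recovery uses 100
participants at the full 141/282 trial counts; the Bayes-factor oracle grid
covers t ∈ [−3, 4] × n ∈ {15, 35, 45}; the demonstration cohort in
`analysis/` has 8 participants per group. The Monte-Carlo enumeration check
runs the full 4000 randomizations against all 70 exact splits.

# Known limitations

* The generator's additive narrow-band component cannot distinguish true
  entrainment from summed evoked responses — neither can scalp EEG.
* The neighbour template is idealized; cluster extents on real recordings
  would depend on the actual cap geometry.
* The muscle detector inside a 40 Hz low-passed band necessarily overlaps
  the beta/gamma EEG range; its cutoff is calibrated on synthetic data.
* EDF/BrainVision readers are not included; recordings use the package's
  own serialized format, and externally read data can enter through
  `new_epoch_set()`.
* IAF/ITF peak-picking inherits the downward 1/f bias of argmax-on-spectrum
  estimators.
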