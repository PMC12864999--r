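Package: entrainr
Title: Pre-Stimulus Sensory Entrainment EEG Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A complete, testable replica of the computational apparatus of a
    pre-stimulus visual sensory-entrainment EEG memory experiment: construction
    of rhythmic and arhythmic luminance modulation waveforms, a synthetic EEG
    and behaviour cohort generator, automated epoching and z-score artifact
    rejection, Hanning-taper time-frequency decomposition with percent-change
    baselining, multitaper resting-state spectra and individual alpha/theta
    frequency extraction, nonparametric cluster-based permutation statistics
    over channel-time-frequency volumes, equal-variance signal-detection
    scoring of recognition memory, and JZS (Cauchy-prior) Bayes factors with a
    sequential open-ended design monitor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
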