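Package: sleeposc
Title: State-Dependent Firing and Oscillation Coactivity Analysis for Sleep Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for chronic multi-regional sleep
    electrophysiology recordings (ventral hippocampus, prelimbic cortex,
    amygdala). Classifies single units as REM- or NREM-preferring with a
    shuffle-null REM-preference index, detects four classes of fast network
    oscillations from LFP (sharp-wave ripples, amygdalar high-frequency
    oscillations, cortical ripples, sleep spindles), quantifies firing-rate
    modulation by sleep state, oscillatory events and aversive stimuli, and
    measures pairwise coactivation with a hypergeometric Z-score.  Includes
    spike-train quality metrics, cross-correlogram based cell typing with
    jitter surrogates, a Steel-Dwass all-pairs post hoc test, and a
    synthetic-session generator with ground truth so every stage is testable
    without external recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
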