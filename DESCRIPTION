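Package: cardiostop
Title: Cardiac-Gated Stop Signal Task Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a stop signal task in which go and stop cues
    are timed to specific phases of the cardiac cycle (systole at 290 ms after
    the R-wave peak, diastole at 10 ms before it). Provides a synthetic cohort
    generator (race-model participants, AR(1) RR-interval series, rendered ECG
    traces, heartbeat-counting and questionnaire data), R-peak detection and
    3-beat median inter-beat-interval prediction for stimulus scheduling,
    one-up/one-down stop-signal-delay staircases, integration-method stop signal
    reaction time (SSRT) estimation, two-pass 2-standard-deviation exclusion
    filters, resting heart rate variability (RMSSD) and interoception indices,
    and a statistics layer (paired t-tests with mean-difference confidence
    intervals, ordinary least squares regression, and a Pearson correlation
    matrix with Benjamini-Hochberg false discovery rate adjustment) that emits
    report tables for the timing-precision, condition-contrast and
    individual-differences analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
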