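Package: stopcascade
Title: Chronometry of Human Action-Stopping from EMG, EEG and TMS Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for the temporal cascade of human action-stopping
    in the stop-signal task. Implements single-trial estimation of the muscle
    cancellation latency (CancelTime) from electromyographic partial bursts,
    behavioral and EMG-based stop-signal reaction time (SSRT) by the
    integration method, a hierarchical Bayesian ex-Gaussian race model with
    trigger failures fitted by Metropolis-within-Gibbs sampling, frontal
    beta-burst detection via narrow-band Hilbert envelopes, chronometry of
    motor-evoked-potential suppression, a race simulator with a ballistic
    response stage, and a permutation test linking beta-burst timing to muscle
    cancellation. A synthetic-data generator with known ground truth emulates
    the task, the EMG, a surrogate EEG channel and MEP amplitudes so that
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
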