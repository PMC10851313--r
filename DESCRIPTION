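Package: contrerp
Title: Regression ERPs for Continuous Reward Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of scalp EEG recorded during continuous
    reward feedback. Provides a behavioural simulator for a bar-growing betting
    task with cue-dependent outcome predictability, a forward EEG synthesizer
    with known ground-truth response kernels, continuous-EEG preprocessing
    (resampling, band-pass and notch filtering, mastoid re-referencing,
    sliding-window artifact masking), overlap-corrected regression-ERP
    estimation with first-derivative Tikhonov regularization and cross-validated
    penalty selection, and group-level inference via spatio-temporal
    cluster-mass permutation tests, zero-lag correlation maps and
    repeated-measures ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
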