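Package: eegfc
Title: Spectral and Phase-Coupling EEG Features for Group Comparison and
    Classification
Version: 0.1.0
Authors@R:
    person("EEG-FC", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for resting-state EEG group studies on the 19-electrode
    10-20 montage: a synthetic two-group cohort simulator with band-limited
    oscillations over 1/f background, von Mises phase-coupled channel pairs
    and instantaneous volume-conduction mixing; Hamming-window FIR filtering
    with zero-phase application and Fz re-referencing; Welch band-power
    features rescaled per 2-s segment; phase-locking value (PLV) and
    corrected imaginary PLV (ciPLV) connectivity over all channel pairs;
    mass-univariate Wilcoxon rank-sum tests with Benjamini-Hochberg false
    discovery rate control and Friedman tests; and an L2-regularised
    logistic-regression classifier evaluated by nested cross-validation,
    explained by correlation-respecting Shapley attributions, with
    leave-one-out per-subject predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
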