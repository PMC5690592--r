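Package: feit
Title: Separation of Cardiac and Respiratory Signals in Functional EIT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of functional electrical impedance tomography (EIT)
    pixel movies of the thorax: adaptive two-stage spectral separation of
    cardiac and respiratory impedance components using zero-phase FIR
    band-pass filters, spatial separation of heart and lung by
    cross-correlation phase mapping with morphological cleanup, per-cycle
    amplitude extraction (cardiac amplitudes during breathing and apnea,
    respiratory amplitudes, spirometric tidal volumes), and nonparametric
    repeated-measures statistics for comparing body positions (Friedman
    test with Conover post-hoc, Wilcoxon signed rank, Pearson correlation).
    Includes a synthetic thorax-movie generator with per-cycle ground truth
    so that every stage of the pipeline can be validated without real EIT
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    nortest,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
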