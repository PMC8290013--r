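Package: fmtheta
Title: Frontal-Midline Theta Dynamics and Cross-Strategy Decoding for Cognitive Control EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for frontal-midline theta (4-8 Hz)
    oscillations across cognitive control strategies. Provides a synthetic
    generator for epoched multi-channel EEG with 1/f background noise and
    stimulus-locked theta bursts, complex Morlet wavelet time-frequency
    decomposition with baseline-normalized dB power (ERSP) and inter-trial
    coherence (ITC), frontal-midline region-of-interest summaries,
    single-trial linear discriminant decoding of control versus target trials
    with cross-strategy generalization and FDR-controlled group inference, and
    behavioral/individual-differences statistics (repeated-measures ANOVA with
    Greenhouse-Geisser correction, Bonferroni post-hocs, residualized Pearson
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car,
    optparse,
    withr
Config/testthat/edition: 3
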