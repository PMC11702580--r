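Package: vipe
Title: Simulation and Analysis of Dopaminergic Value and Identity Prediction Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing ventral tegmental area (VTA)
    single-unit recordings in a blockwise odor-guided choice task in which the
    number of reward drops (value) and the reward flavor (identity) are shifted
    independently. Provides a task generator (block plans, constrained
    pseudorandom odor sequences, behavioral choice/reaction-time simulation), an
    inhomogeneous-Poisson spike-train simulator driven by a drop-wise
    Rescorla-Wagner value and identity prediction-error rate model with
    control, hippocampus-lesion and orbitofrontal-lesion presets, a
    waveform-based putative dopamine neuron classifier (leave-one-out cluster
    assignment on spike half-duration and amplitude ratio), a
    reward-responsiveness screen, and early-versus-late difference-score
    statistics (Wilcoxon signed-rank summaries, factorial ANOVAs, chi-square
    tests on classification proportions), plus a plain-text session bundle
    format tying the stages together reproducibly.
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
    optparse
Config/testthat/edition: 3
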