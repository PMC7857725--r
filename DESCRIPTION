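Package: premovoc
Title: Premotor Selectivity Analysis for Cued Vocal and Manual Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for single-unit recordings from a vocal-versus-
    manual go/nogo detection task. Provides a session data model with
    event-aligned spike and eye-trace extraction, a ground-truth-labeled
    synthetic session generator (inhomogeneous-Poisson units, saccadic eye
    traces, block-alternating behavior), signal-detection behavioral
    summaries (d-prime), saccade and fixation confound screening, premotor
    response-type classification with PSTH latency estimation, sliding-window
    AUROC coding-quality analysis with permutation significance,
    population-overlap statistics, and Gaussian-process factor analysis
    (GPFA) of pseudo-population state-space trajectories with
    within- and cross-response distance curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
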