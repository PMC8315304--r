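Package: perimove
Title: Peri-Movement Timing Analysis of Neural Population Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deciding whether neural population activity
    carries a fixed-latency, movement-locked timing signal rather than a
    cue-locked or ramp-to-threshold signal. Implements delta-F/F normalization
    of calcium-imaging traces, movement-aligned response classification
    (Friedman test with Tukey-Kramer post hoc), slope-sum-function onset
    detection with simulation-based calibration, trial-bootstrap onset
    statistics with per-animal weighting, subthreshold membrane-potential
    trajectory analysis for whole-cell recordings, peri-event firing-rate
    change detection for sorted units, behavioral motion-index movement
    detection and push-vector classification, and image-domain quantification
    of pharmacological spread and dual-channel overlap. A synthetic-data
    generator emulates every input modality with ground truth so each stage
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
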