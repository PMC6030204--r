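Package: gonogo2p
Title: Analysis of Two-Photon Calcium Imaging During Go/No-Go Visual Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing volumetric two-photon calcium imaging
    recorded while head-fixed mice perform a go/no-go visual
    discrimination task with interleaved engaged and passive blocks.
    Covers movie preprocessing (rigid motion correction, activity-map
    segmentation, neuropil subtraction, mode-based dF/F normalisation,
    cross-session ROI alignment), behavioural performance (d-prime with
    truncation, lick-bout detection, session criteria), ROC-based
    selectivity and modulation indices with permutation significance,
    a lagged-predictor ridge encoding model with component
    decomposition and bootstrap model comparison, Naka-Rushton
    contrast-response fitting with a bootstrap goodness-of-fit test,
    and before/after contingency-reversal classification of stimulus-
    versus choice-coding neurons. A synthetic session generator with
    planted ground truth (neuron archetypes, calcium kinetics, task
    timing) makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
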