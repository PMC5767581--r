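Package: cmcoh
Title: Corticomuscular Coherence Analysis for EEG-EMG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and statistical comparison of corticomuscular
    coherence (CMC) between scalp EEG and surface EMG during steady
    voluntary contraction. Provides EDF/EDF+ reading and writing with
    event annotations, zero-phase FIR band-pass filtering, ICA-based
    artifact removal with automatic blink/ECG/line-noise scoring,
    spherical-spline surface-Laplacian current source density,
    multitaper coherence spectra with degrees-of-freedom bookkeeping,
    beta-band coherence topographies with peak-electrode selection, and
    a nonparametric cluster-based permutation test of coherence
    differences between conditions using a bias-corrected z-spectrum
    and a Monte Carlo p-value. A synthetic-data module simulates
    sessions of coupled EEG/EMG/force recordings with a closed-form
    expected coherence so every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
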