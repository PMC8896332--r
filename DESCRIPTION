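Package: perturbex
Title: Perturbational EEG Complexity and Spectral State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of multichannel perturbational electroencephalography:
    preprocessing (Butterworth band-pass, decimation, epoching, baseline
    correction, artifact rejection), Morlet time-frequency power with
    bootstrap max-statistic significance masks, inter-trial phase clustering
    (ITPC) and its drop time, inter-site phase clustering (ISPC) connectivity
    with Gaussian v-test rejection of volume conduction, the state-transition
    perturbational complexity index (PCIst) over full and sliding response
    windows, spontaneous-EEG periodograms with 1/f spectral exponent and
    HF/LF activation ratio, and group-level repeated-measures statistics.
    Includes a synthetic multichannel EEG/ERP session generator with known
    ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car,
    Matrix,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
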