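Package: meapipe
Title: Spike-Train Feature Extraction and Synchrony Analysis for
    Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-well multi-electrode array (MEA)
    recordings of cultured neural networks: threshold-based spike detection
    on filtered voltage traces, max-interval burst detection, electrode
    inclusion and noise filtering, per-well spiking and bursting features,
    SPIKE-distance based pairwise synchrony with surrogate normalization,
    and fold-change normalization of treated wells against baseline and
    age-matched control wells with repeated-measures group statistics.
    Includes a synthetic plate generator with programmable treatment
    effects for validation and power analysis, and readers/writers for an
    open HDF5/CSV spike-timestamp dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    rhdf5,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
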