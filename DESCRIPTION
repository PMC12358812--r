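Package: mesogaba
Title: Mesoscale Wide-Field GABA Imaging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for mesoscale wide-field imaging of cortical
    GABA dynamics with a dual-wavelength (fluorescence/reflectance) strobed
    camera. Implements de-interleaving and channel verification, pixel-wise
    hemodynamic regression (F - alpha*R), delta-F/F computation, zero-phase
    band-pass filtering, trial-averaged sensory-evoked response features
    (peak amplitude, time-to-peak, 50%-decay time), EMG-based motion
    exclusion, rule-based wake/NREM/REM sleep scoring from EMG, hippocampal
    LFP and video motion energy, brain-state-resolved seed-pixel and
    interhemispheric ROI connectivity, and detection of spontaneous GABA
    transients. Ships a ground-truth-annotated synthetic-data generator that
    emulates the recordings so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
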