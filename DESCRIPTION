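Package: hrvclean
Title: Artifact Correction for Beat-to-Beat Heart Rate Variability Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Cleans beat-to-beat (RR) interval recordings from wearable
    heart-rate monitors. Provides stochastic correction of spuriously long
    intervals caused by missed beats, heart-rate-guided stochastic filling of
    runs of missing beats, reference filters (sliding median, threshold-based
    cubic interpolation, cubic-spline gap filling), the eight standard
    heart-rate-variability measures (RMSSD, SDNN, SDSD, total/LF/HF spectral
    power, Poincare SD1/SD2), a synthetic paired RR/heart-rate signal
    generator, and an artifact-injection harness that quantifies the error
    each correction method introduces into the HRV measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
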