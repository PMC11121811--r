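Package: wingbeatr
Title: Insect Wingbeat-Frequency Extraction, Clustering and Temperature Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optical insect-sensor data: simulation of
    transit waveforms and event-level field campaigns, detection of transit
    events in voltage traces, FFT-based wingbeat-frequency retrieval, optical
    extinction cross-sections for wings and body, Gaussian-mixture and K-means
    clustering with BIC model selection, per-cluster temperature-binned linear
    fits of wingbeat frequency, and a general quadratic temperature-correction
    model that shifts measured wingbeat frequencies to a reference temperature.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mclust,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
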