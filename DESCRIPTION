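Package: hrrhythm
Title: Trend Analysis of Stress-Related Heart-Rate Rhythm from Wearable Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for 1 Hz smartwatch heart-rate recordings with
    self-reported stress events: physiologic range filtering, 20-minute
    stress/normal window extraction with per-participant balancing,
    Augmented Dickey-Fuller stationarity testing and first-order differencing,
    autocorrelation features (significant-lag and peak counts at the 95%
    confidence band), detrended fluctuation analysis (DFA) scaling exponents,
    Mann-Kendall trend tests, and paired per-participant stress-versus-normal
    comparisons. Includes a synthetic cohort generator with tunable long-range
    correlation structure so the full pipeline is testable without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tibble,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
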