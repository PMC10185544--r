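Package: ssepmri
Title: Integrate Somatosensory Evoked Potential Features with MRI Spinal
    Cord Compression Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the combined analysis of preoperative somatosensory
    evoked potentials (SSEP) and MRI-based spinal cord compression grading.
    Provides event-related potential averaging, peak-to-peak amplitude and
    latency extraction, short-time-Fourier-transform time-frequency power in
    a fixed region, cord compression ratio (CCR) and maximum spinal cord
    compression (MSCC) morphometry with 0-3 compression grading,
    threshold-based neuro-abnormality classification against control
    references, per-grade contingency statistics (exact two-sided Fisher
    test, Kendall tau-b, Kruskal-Wallis H, Mann-Whitney U), a seeded
    synthetic cohort generator for end-to-end validation, and a reproducible
    pipeline that assembles the per-grade patient-distribution report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
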