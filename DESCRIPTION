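Package: nmosdmri
Title: MRI Lesion Features Distinguishing AQP4-Seropositive NMOSD from
    Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing MRI lesion-feature data in the differential
    diagnosis of aquaporin-4 antibody seropositive neuromyelitis optica
    spectrum disorder (NMOSD) versus multiple sclerosis (MS). Provides a
    typed lesion-feature catalogue, per-patient first/ever feature
    aggregation with missing-scan handling, Haldane-Anscombe corrected
    odds ratios, rule-based imaging criteria (Paty, Barkhof, configurable
    external rule sets), weighted summative NMOSD/MS diagnostic scores with
    a combination-ratio rule, a decision-tree engine, a greedy score-model
    search, opposite-class weighted confusion-matrix metrics, a 44
    hemi-vertebral-level spinal cord lesion heat map, and a calibrated
    synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
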