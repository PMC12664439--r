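Package: lymphdsb
Title: DNA Double-Strand Break Scoring for Internal Ex Vivo Blood Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-scale model of radiation-induced DNA double-strand breaks (DSB)
    in lymphocyte nuclei during internal ex vivo irradiation of whole blood.
    Provides random non-overlapping sphere packing of lymphocytes in a
    cylindrical vial, phase-space particle record handling (translation to
    cell-local frames, merging, anti-neutrino stripping, CSV I/O), a seeded
    synthetic generator of low-LET electron and high-LET alpha energy-deposition
    tracks through a spherical nucleus, a DBSCAN-based strand-break clustering
    scorer with SSB/DSB classification, dosimetry conversions (per-transformation
    energy scoring with history-by-history uncertainty, activity and blood dose,
    lymphocyte-nucleus dose coefficients, DSB per cell per mGy), alpha-track
    counting with detectability thresholds and linear DSB density, and
    cluster-complexity reporting with an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
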