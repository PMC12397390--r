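Package: accelPD
Title: Segmental Moment Analysis of Rodent Accelerometry for Parkinsonian Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for continuous 3-axis accelerometer recordings
    from rodent disease models. Reduces raw per-axis signals to acceleration
    magnitudes, computes the first four statistical moments on non-overlapping
    one-minute segments, screens datasets with a PCA latent projection and the
    MAD-median robust outlier rule, and compares groups with a nonparametric
    two-sample battery (Mann-Whitney U, Kolmogorov-Smirnov,
    Baumgartner-Weiss-Schindler) under a literal Holm-Bonferroni adjustment
    with sequential rejection. Includes a calibrated synthetic-cohort
    generator emulating sham and 6-OHDA-lesioned rat activity so the full
    pipeline is testable without animal data, plus the published apomorphine
    rotation table and group-level summary statistics as package data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
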