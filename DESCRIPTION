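Package: cagewalk
Title: Supervised and Unsupervised Behavioral Phenotyping for Home-Cage
    and Gait Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies rodent behavior from long home-cage video assays
    and walkway gait recordings. Reads pose-estimation tables in the
    DeepLabCut wide-CSV dialect, applies likelihood filtering with
    interpolation, and computes supervised feature batteries (activity,
    stretch-attend posture, acclimation, habituation to stimuli, cage
    occupancy). Summarizes behavioral syllable label sequences (bout
    frequency, duration, transition matrices, per-period windows), and
    derives walkway gait parameters including print geometry, support
    phases, base of support, and normal step sequence patterns with
    run-compliance filtering. Feature batteries are assembled into
    125-parameter behavioral profiles per experimental group and
    clustered with PCA-loading-weighted Ward linkage. A synthetic-cohort
    simulator with configurable group effects provides a
    parameter-recovery test surface, and a statistical battery
    (Shapiro-Wilk gating, two-way ANOVA with Tukey HSD, rank-sum,
    Kruskal-Wallis with Dunn post hoc) supports group comparison and
    significance-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
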