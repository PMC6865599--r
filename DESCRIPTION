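Package: leidar
Title: Leading-Eigenvector Dynamics Analysis of Dynamic Functional Connectivity
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers recurrent functional-connectivity (FC) states from
    parcellated BOLD time series using leading-eigenvector dynamics analysis
    (LEiDA): band-pass filtering, Hilbert instantaneous phases, per-frame
    phase-coherence matrices, their leading eigenvectors, and k-means
    partitioning of the pooled eigenvectors into FC states across a sweep of k.
    Computes per-scan dynamical statistics of the states (fractional occupancy,
    mean lifetime, switching frequency, switching profiles, Shannon entropy)
    and compares them between groups with permutation-based t tests, paired
    within-group tests, covariate-adjusted (Freedman-Lane) regression, and
    group-by-condition interaction tests, with per-partition Bonferroni
    correction and Hedges' g effect sizes. Includes a synthetic-cohort
    generator with a hidden Markov state sequence over planted phase-community
    patterns, so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
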