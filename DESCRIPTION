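Package: qhtscyp
Title: Quantitative High-Throughput Screening Analysis for CYP Inhibition Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end analysis of quantitative high-throughput screening (qHTS)
    cytochrome P450 inhibition data in 1536-well format: plate normalization
    against DMSO and positive-control wells, DMSO-plate background pattern
    correction, plate quality control (signal-to-background, CV, Z'-factor),
    four-parameter Hill fitting of 15-point concentration-response series,
    Tox21-style curve classification and curve ranks, triplicate
    reproducibility calls, compound activity outcomes, self-organizing-map
    clustering of chemical fingerprints on a hexagonal grid, and Fisher's
    exact enrichment of structural classes. Includes a synthetic screen
    generator with known ground truth that emulates the study design
    (control layout, titration series, three runs, plate noise and spatial
    background patterns, luciferase counter-screen interference) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
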