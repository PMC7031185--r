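Package: lipidhilic
Title: In Silico Lipid Database, Annotation and Differential Statistics
    for HILIC LC-MS Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for class-resolved HILIC LC-MS lipidomics
    of cultured cells: construction of an in silico lipid mass database
    (elemental formulas, monoisotopic masses, adduct m/z) for
    glycerophospholipids, sphingomyelin and cholesterol; carbon-13
    de-isotoping of centroided feature tables; lipid annotation by
    retention-time class windows and m/z matching; percent-abundance
    differential statistics with per-species two-way ANOVA and
    Dunnett-corrected many-to-one comparisons; fatty-acyl double-bond and
    chain-length aggregation; principal component analysis; plus
    calibration-curve cholesterol quantitation and geNorm reference-gene
    normalization of qPCR takeoff/amplification data. A seeded
    synthetic-data generator emulates the two-time-point, three-dose cell
    treatment design so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    tidyr,
    tools,
    utils,
    stats,
    withr
Suggests:
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
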