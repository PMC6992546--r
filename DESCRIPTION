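Package: honeyprint
Title: Elemental Fingerprint Authentication of Mono-Floral Honey
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: One-class chemometric verification of botanical-variety and
    country-of-origin claims for mono-floral honey from multielement
    mass-fraction fingerprints. Provides NIPALS principal component models
    per variety-country class with DModX distance-to-model membership at an
    F-based critical limit, loading-plot variable elimination, Wold-style
    cross-validated Q2, two-class PLS discriminant models to resolve
    overlapping classes, the full label-verification cascade with
    sensitivity and specificity reporting, ANOVA-based reproducibility
    statistics for a days-by-replicates design, and a seeded synthetic-data
    generator that emulates published per-class element ranges, detection
    limits and film-blank contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
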