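Package: trailrisk
Title: Re-Identification Risk of Longitudinal Residential Trails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates population uniqueness of individuals on demographic
    quasi-identifiers (date of birth, postal code, gender), including
    multi-year residential postal-code trails, across a generalization
    lattice. Uniqueness is computed exactly from full populations or
    estimated from simple random samples with the Zayatz sample-uniques
    estimator. Includes a synthetic population-registry generator with
    Canadian-style postal geography, residential mobility, births, deaths
    and data-quality corruption, so the whole pipeline can be exercised and
    calibrated without access to confidential registry data; plus an
    aggregate-counts estimator that recovers per-postal-code uniqueness by
    uniform redistribution of birthdays within birth years.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
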