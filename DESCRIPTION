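Package: chemoextract
Title: Chemometric Optimization of Botanical Extractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-of-experiments tools for optimizing extraction of plant
    bioactives with chemometric read-outs. Builds three-level full factorial
    and face-centered central composite designs, fits second-order response
    surface models with pooled-variance coefficient tests, hierarchical model
    reduction and lack-of-fit ANOVA, condenses multi-peak chromatographic
    response tables to a single composite response by principal component
    analysis, analyses UV-Vis spectra by standard normal variate pretreatment
    and ANOVA-simultaneous component analysis (ASCA) with permutation and
    bootstrap significance, and estimates DPPH radical-scavenging IC50 values.
    Includes seeded synthetic-data generators with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
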