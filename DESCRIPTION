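Package: pmmprofiler
Title: Metabolic Profiling of Phenotype Mammalian MicroArray Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces per-well Biolog Phenotype Mammalian MicroArray (PM-M)
    kinetic optical-density curves and endpoint two-wavelength absorbance
    reads to energy-production summaries (trapezoid AUC, A590-750, log
    scale), compares patient groups against a normative control cohort with
    per-well exact Mann-Whitney tests and Benjamini-Hochberg false discovery
    rate control, classifies single patients against control box-and-whisker
    outer limits, and aggregates per-well outcomes into compound-level trend
    tables, opposite-trend lists and compound-cluster fractions. A seeded
    synthetic-cohort generator with a logistic NADH-production curve model
    makes every stage testable without instrument exports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
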