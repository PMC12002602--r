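Package: oleoflux
Title: Constraint-Based Analysis of Oleaginous Fungal Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based analysis of genome-scale metabolic
    models of oleaginous fungi: model construction and serialization (SBML
    L3V1 with FBC v2, JSON, TSV), biomass-equation assembly from
    macromolecular composition tables with growth-associated maintenance,
    flux balance analysis and parsimonious FBA on a built-in linear
    programming core, minimal-medium carbon-source screening against
    phenotype-microarray plates with concordance scoring, reaction-activity
    classification across media, and FSEOF (Flux Scanning based on Enforced
    Objective Flux) scanning for lipid-production amplification targets with
    gene mapping through gene-protein-reaction rules. Ships synthetic model,
    plate and planted-target generators so the whole pipeline is testable
    without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
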