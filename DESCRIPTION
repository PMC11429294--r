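Package: alcs
Title: Model-Based Design and Simulation of Automated Liquid Clone Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulate and validate automated liquid clone selection
    (ALCS) experiments, in which freshly transformed bacterial populations are
    enriched for antibiotic-resistant transformants by serial passaging in
    liquid medium instead of colony picking.  The package estimates strain
    growth parameters from colony-area time series on agar plates, derives the
    required selection time and the stage/transfer schedule from a
    two-subpopulation exponential growth/death model, simulates stage-wise
    enrichment with dilution transfers (optionally with carrying capacity and
    replicate-level growth-rate heterogeneity), and fits the model back to
    stage-wise flow-cytometry population fractions by Levenberg-Marquardt
    least squares.  A seeded synthetic-data generator produces every input the
    pipeline consumes, so all components are testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
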