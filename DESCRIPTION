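Package: propolistox
Title: Toxic Element Screening and Health Risk Assessment for Raw Propolis
Version: 0.1.0
Authors@R: person("Propolistox", "Maintainers", email = "maintainers@propolistox.org", role = c("aut", "cre"))
Description: Tools for biomonitoring studies that quantify toxic elements
    (As, Cd, Pb, Mn) in raw propolis by ICP-OES and evaluate the human
    health implications of consuming it. Covers quality-control acceptance
    of the analytical method (recovery and precision bands), handling of
    left-censored concentrations relative to LOD/LOQ, detection-frequency
    and regulatory compliance screening against EFSA and Latin American
    standards, chemometric characterization (Pearson correlation, PCA,
    Ward hierarchical clustering), and deterministic dietary exposure and
    risk assessment (average daily dose, hazard quotient, carcinogenic
    risk with screening bands). Includes a seeded synthetic-data generator
    with correlated lognormal margins for testing the pipeline beyond the
    bundled 12-sample fixture, and a command-line report runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
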