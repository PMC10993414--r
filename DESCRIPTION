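Package: mitotox
Title: Mitochondrial Toxicity Screening from Multiplexed Plate Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Data evaluation for a multiplexed in vitro mitochondrial
    toxicity screen that reads mitochondrial membrane potential (MMP,
    red/green dye-aggregate ratio), cytotoxicity (cell counts) and
    oxidative stress (ARE-driven luciferase) from 384-well plates.
    Provides plate-table input/output, per-well effect quantification
    against solvent controls, constrained four-parameter log-logistic
    concentration-response fitting with cytotoxicity masking rules
    (IC10, EC10, EC_IR1.5), baseline-toxicity QSAR prediction with
    toxic-ratio and specificity-ratio classification, bioanalytical
    equivalent concentration (BEQ) iceberg accounting for water-extract
    mixtures under concentration addition, and a synthetic plate-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
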