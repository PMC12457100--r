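Package: gliomatwin
Title: Tumor-Macrophage Dynamics, Radiotherapy, and Digital-Twin Trials in Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dynamical model of glioma growth driven by tumor-macrophage
    interactions, with separate tracking of brain-resident microglia and
    infiltrating monocyte-derived macrophages. Ionizing radiation is modelled
    as an impulsive transfer of cells to damaged compartments, with
    microenvironment remodelling (escalated monocyte influx and inflammation
    flux). The package fits per-subject tumor proliferation rates and
    radiosensitivities to longitudinal volume data by RMSE minimization,
    computes in silico biomarker panels, generates synthetic cohorts with the
    statistical structure of small-animal glioma experiments, and runs paired
    digital-twin in silico trials of radiotherapy and myeloid-targeted
    immunotherapies (anti-CD47, alpha-CD49d, CSF-1R inhibition) with
    Kaplan-Meier, log-rank, effect-size, and ROC summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
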