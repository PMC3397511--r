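Package: qsar3d
Title: Grid-Based 3D-QSAR with CoMFA/CoMSIA Fields, PLS and External Validation
Version: 0.1.0
Authors@R:
    person("QSAR3D", "Maintainers", email = "qsar3d@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for ligand-based three-dimensional quantitative
    structure-activity relationship (3D-QSAR) modelling of small-molecule series:
    scaffold-based rigid superposition (Kabsch), comparative molecular field
    analysis (CoMFA) steric/electrostatic probe fields and comparative molecular
    similarity indices (CoMSIA) Gaussian fields on a shared lattice, partial
    least squares (PLS/NIPALS) regression with leave-one-out cross-validation,
    a full external-validation battery (r2_pred, through-origin regressions,
    Roy's r2_m, RMSEP, the five-condition acceptability gate, y-randomization,
    bootstrap and repeated k-fold resampling), StDev*Coeff contour extraction
    with OpenDX export, and a synthetic planted-coefficient benchmark generator.
    Ships a 71-compound thiourea MK-2 inhibitor activity table with its printed
    train/test split as the worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as "python" on the
    PATH, for SMILES/MOL2 input, charge assignment and SMARTS matching.
Config/testthat/edition: 3
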