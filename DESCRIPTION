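Package: mindyx
Title: Nonlinear Whole-Brain Dynamical Modeling of Joint Resting-State and Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits individualized nonlinear neural-mass network models jointly to
    resting-state and task fMRI time series. Provides Wiener deconvolution of
    hemodynamic signals, sparse-plus-low-rank regularized system identification by
    minibatch gradient descent, linear baseline models (VARX, ARX, GLM), noise-free
    and noise-driven forward simulation, attractor-landscape identification (stable
    equilibria, limit cycles, topology classification, rest-to-task bifurcation),
    population motif clustering with instability-based model selection, per-subject
    occupancy and distance features, and validation statistics (cross-validated one-step
    R-squared, functional connectivity with Fisher z, intraclass correlation, task GLM
    coefficients, behavioral regression models). Includes a synthetic-session generator
    emulating block-design working-memory experiments so the full pipeline is testable
    without access to restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
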