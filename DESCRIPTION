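Package: thzburnmap
Title: Terahertz Time-Domain Spectroscopic Imaging Pipeline for Burn
    Severity Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for terahertz (THz)
    time-domain spectroscopic reflection imaging of graded burn wounds
    behind an imaging window. Provides a physics-based scan simulator
    (double-Debye skin dielectrics, Fresnel reflection, Fabry-Perot
    window echoes, punch-biopsy air gaps), maximal-overlap discrete
    wavelet transform denoising with level-dependent hard thresholds,
    SNR-regularized Wiener deconvolution, spectral-band image formation,
    echo-phase biopsy masking, randomized region-of-interest observation
    tables, and a cross-validated one-vs-all classifier harness (SVM,
    naive Bayes, regularized LDA, AdaBoosted LDA) with Bayesian
    hyperparameter search, ROC/AUC reporting, and one-way ANOVA on
    spectral band areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    data.table,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
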