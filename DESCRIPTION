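Package: dcefit
Title: Quantitative DCE-MRI Pharmacokinetic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise quantitative analysis of dynamic contrast enhanced
    MRI (DCE-MRI). Provides variable-flip-angle T1 relaxometry with the
    spoiled gradient echo (SPGR) signal model, inversion of dynamic signal
    to longitudinal relaxation rate and tracer concentration, the
    plasma-only, Standard and Extended Tofts-Kety compartment models with
    analytic Jacobians, an in-package Levenberg-Marquardt solver with a
    deterministic parallel voxelwise driver, signal-enhancement-ratio
    masking and parameter clamping, QIBA-style digital reference object
    phantom generation with Rician noise injection, accuracy metrics
    (RMS/max percent error, Lin's concordance correlation coefficient),
    MAT v5 and DICOM input/output, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite
Config/testthat/edition: 3
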