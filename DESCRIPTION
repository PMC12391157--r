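Package: pahemo
Title: Pulmonary Artery Hemodynamics and Right-Ventricular Remodeling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale pipeline for pulmonary-artery hemodynamics in repaired
    tetralogy of Fallot: synthetic three-branch pulmonary artery geometry and
    pulsatile flow generation with controlled regurgitation, centerline
    curvature and tortuosity metrics, inlet/outlet boundary-condition
    construction (Fourier waveform decomposition, parabolic inlet profile,
    parallel resistance outlets in indexed Wood units), an analytic
    Poiseuille/Womersley wall-shear engine, post-processing into time-averaged
    wall shear stress and oscillatory shear index with per-segment summaries,
    and downstream association analyses (adjusted linear regression with
    Benjamini-Hochberg correction, Cox proportional hazards with Schoenfeld
    diagnostics, ROC-derived cutoffs, Kaplan-Meier stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
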