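Package: msti
Title: Multisequence Thrombus MRI Simulation, Parametric Mapping, and Lysis Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative multisequence thrombus imaging (MSTI) of
    deep venous thrombosis. Generates seeded synthetic two-group (lysed versus
    nonlysed) phantom cohorts with Rician acquisition noise; computes voxelwise
    parametric maps (T1 by 3-parameter inversion-recovery fitting with
    Look-Locker correction, magnetization transfer ratio, apparent diffusion
    coefficient with a physiological exclusion rule); extracts slice-wise
    thrombus features; and predicts thrombolysis success with a combined-cutoff
    rule or a logistic lysis-probability model, including probability heat-map
    volumes. A statistics suite (Mann-Whitney U with exact enumeration, ROC with
    Youden threshold selection, diagnostic metrics, Bland-Altman, Cohen kappa)
    supports cohort evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
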