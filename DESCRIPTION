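Package: hipspect
Title: Quantitative SPECT/CT Femoral-Head Perfusion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies femoral-head perfusion from SPECT/CT-like
    photon-count volumes using spherical regions of interest, computes
    head-to-head and head-to-acetabulum uptake ratios, and evaluates
    their diagnostic accuracy for predicting osteonecrosis of the
    femoral head after femoral neck fracture: 2x2 accuracy metrics,
    likelihood ratios with log-method confidence intervals, ROC curves
    with Youden-index cutoff derivation, and DeLong comparison of
    correlated AUCs. A synthetic hip-phantom and cohort generator makes
    the full pipeline reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
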