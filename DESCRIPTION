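Package: perirad
Title: Peritumoral CT Radiomics Risk Modelling for Immunotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for predicting progressive disease
    versus disease control under first-line pembrolizumab from pre-treatment
    CT. Builds intra- and peritumoral (Core / Core-Plus-Edge / Ring) masks
    around seed-annotated lung lesions, extracts a documented bank of 2-D
    shape, intensity, radial and texture radiomic features per axial slice,
    filters and selects features (sequential forward selection, mRMR,
    ReliefF), fits grouped nested-cross-validated logistic risk models
    including a published four-variable risk calculator, converts per-slice
    risk scores into lesion- and patient-level calls by frequency
    thresholding, and compares predicted risk groups with Kaplan-Meier /
    log-rank survival analysis. A synthetic-cohort generator with planted
    peritumoral signal makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    generics,
    glmnet,
    survival,
    EBImage,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
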