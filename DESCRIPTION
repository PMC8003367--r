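Package: lnradiomics
Title: ADC Histogram Radiomics and Decision-Tree Prediction of Pelvic Lymph-Node Metastasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided workflow for predicting pelvic lymph-node metastasis in
    endometrial cancer from diffusion-weighted MR imaging. Provides seeded
    region-growing lymph-node segmentation with automatic morphometry, first-order
    ADC histogram radiomics (109 clinical and radiomic parameters with bladder
    normalisation), fixed printed decision rules (RadScore, RadSignature, ADC and
    short-axis threshold models), de-novo weighted CART induction with
    cost-complexity pruning and repeated cross-validation, and a diagnostic-accuracy
    suite (exact binomial confidence intervals, exact McNemar, DeLong paired AUC,
    bootstrap, stratified splitting, patient-level aggregation, ESGO-ESMO risk
    groups). Synthetic MR phantoms and synthetic cohorts make the full pipeline
    testable without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    rpart,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
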