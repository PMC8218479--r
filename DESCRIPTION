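Package: abeT1
Title: Semi-Quantitative T1-Weighted MRI Diagnosis of Neonatal Acute
    Bilirubin Encephalopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the semi-quantitative diagnosis of neonatal acute
    bilirubin encephalopathy (ABE) from T1-weighted MRI. Implements
    normalized globus-pallidus and subthalamic-nucleus intensity scores
    (mean ROI intensity divided by mean anterior subcortical white-matter
    intensity), from-scratch ROC construction with Youden-index cutoff
    selection, diagnostic classification metrics with the field's display
    conventions, inter-rater agreement (Fleiss' kappa) and accuracy
    comparisons, cohort covariate statistics including covariate-adjusted
    group tests, a synthetic phantom-image cohort generator that emulates
    the clinical study design, and a compact residual convolutional
    network with class-activation mapping for desk-scale image
    classification experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
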