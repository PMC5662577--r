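Package: vicad
Title: Computer-Aided Regional Vascularity Assessment of Thyroid Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the vascularity of thyroid nodules in colour Doppler
    ultrasound still images. A manually outlined nodule is recovered as a
    binary region of interest (ROI), partitioned into peripheral and central
    regions by contour-preserving inward offsetting (iterative raster erosion,
    with an exact Euclidean distance-transform mode as geometric reference),
    and the vascular index (VI, the percentage of colour-coded flow pixels) is
    computed overall and per region. Cohort-level utilities derive the optimum
    offset level from per-offset Welch two-sample tests, fit ROC cut-offs by
    the Youden index, and score rule-based malignancy classifiers that combine
    VI with grey-scale ultrasound features. A synthetic phantom and cohort
    generator provides ground-truth data for validation, and a command-line
    interface ties the stages into a batch tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
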