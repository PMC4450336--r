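Package: shrinkreg
Title: Deformable Registration of Shrinking Tumors in Head-and-Neck CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Registers planning and posttreatment head-and-neck CT studies in
    the presence of radiation-induced tumor shrinkage. Planning-CT tumor
    intensities are modified with a linear-quadratic cell-survival model
    driven by the planned dose, rescaled to match the posttreatment
    tumor-region intensity sum, and the pair is then registered with a
    single-resolution symmetric-force Demons algorithm initialized by a
    bone-driven translation-only rigid registration. Includes readers and
    writers for DICOM CT series, RT-DOSE and RT-STRUCT objects, NIfTI and
    MetaImage volumes, a synthetic head-phantom generator with known
    ground-truth deformations for validation, and Dice-overlap and
    displacement-recovery evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
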