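Package: motiliomics
Title: Linking MRI Radiomics to Glioblastoma Cellular Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline relating quantitative imaging features of
    contrast-enhancing brain tumors to the random motility coefficient of
    their resected cells. Includes per-cell mean-squared-displacement analysis
    and random-motility-coefficient estimation from time-lapse tracks, a
    107-feature radiomics extractor (first-order, 3D shape, GLCM, GLRLM,
    GLSZM, NGTDM, GLDM) with cohort histogram matching and adaptive intensity
    binning, bootstrap-forest feature ranking, adaptive-lasso regression,
    leave-one-out cross-validation against a mean-value baseline, and
    permutation-based significance testing. A synthetic cohort generator with
    planted feature-motility relationships makes every stage testable without
    patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    ranger,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
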