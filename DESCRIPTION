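Package: msradiomics
Title: Brain Tissue Radiomics for Multiple Sclerosis Classification on
    Conventional and Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a brain-tissue radiomics pipeline
    that discriminates multiple-sclerosis patients from healthy controls
    using first-order and texture features (GLCM, GLRLM, GLSZM, NGTDM, GLDM)
    extracted from white matter, normal-appearing white matter and gray
    matter on conventional (T1w) and quantitative (PD, MT, R1, R2*) MRI.
    Includes a seeded synthetic-cohort generator (multi-channel ellipsoid
    brain phantoms with tissue probability maps and focal lesions),
    preprocessing (isotropic resampling, probability-map thresholding,
    bias-field correction, TIV normalization), fixed-bin-number feature
    extraction, univariate screening, balanced-bootstrap stability feature
    selection with random-forest recursive feature elimination, LR/SVM/RF
    model evaluation on balanced bootstrap cohorts with DeLong AUC
    comparison, a permutation-test overfitting audit, an external-validation
    harness, and voxelwise feature saliency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    glmnet,
    e1071,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
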