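Package: pettex
Title: Texture Analysis of Dual-Resolution Breast PET Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for comparing the tumor-characteristic
    classification power of high-resolution dedicated breast PET (dbPET) and
    whole-body PET/CT texture features. Provides seedable dual-resolution
    phantom simulation (Gaussian point-spread blur, partial-volume rebinning,
    additive noise), 40%-of-SUVmax relative-threshold lesion delineation with a
    background-extractability exclusion rule, 64-level intensity quantization,
    38 texture features from the intensity histogram and four 3D gray-level
    texture matrices (GLCM, GLRLM, GLZSM, NGLDM) plus conventional SUV metrics
    (SUVmax, SUVmean, MTV, TLG), per-feature Wilcoxon group comparisons,
    principal-component feature reduction with the Kaiser eigenvalue rule, and
    ROC/AUC classification with paired DeLong curve comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
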