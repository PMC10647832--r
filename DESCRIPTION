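Package: mpRadRisk
Title: Radiomic and Clinical-Genomic Risk Classification of Prostate mpMRI Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-biopsy risk classification of prostate lesions from
    multiparametric MRI. Implements reference-tissue intensity normalization
    of T2-weighted and high b-value volumes, first-order histogram and
    voxel-wise 3D Haralick texture radiomics (5x5x5 sliding window, local
    0-255 rescaling, 128-bin grey-level co-occurrence matrices) over lesion
    and normally-appearing tissue regions, clinical-genomic risk labeling
    (NCCN group, Decipher category, Spratt three-tier score), adaptive-LASSO
    penalized logistic models combining clinical and radiomic variables, and
    ROC-based evaluation with Venkatraman-Begg curve comparison and
    bootstrap optimism-corrected AUC. A synthetic phantom-cohort generator
    provides fully reproducible test data with the class structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    glmnet,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
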