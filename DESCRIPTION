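Package: radvpi
Title: CT Radiomics Signature for Visceral Pleural Invasion in Early Lung Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible radiomics pipeline for discriminating visceral
    pleural invasion (VPI) in stage I lung adenocarcinoma from thin-section
    CT. Extracts a 308-feature catalog (shape, histogram, GLCM and GLRLM
    texture, coiflet wavelet subband energies) from 3D volumes of interest,
    filters features by concordance-correlation reproducibility and
    correlation redundancy, ranks them by SVM recursive feature elimination
    with a cumulative contribution-weight stop, trains an RBF-SVM sigmoid
    probability signature under repeated stratified ten-fold
    cross-validation, derives a Youden-optimal ROC cut-off for risk
    stratification, and reports the full set of diagnostic and association
    statistics (DeLong AUC, confusion metrics, logistic odds ratio, AIC,
    concordance index, rank tests, contingency summaries). Includes a
    synthetic cohort generator (feature tables and 3D nodule phantoms with
    perturbed re-segmentations) so the whole pipeline runs end to end
    without any private imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    pROC,
    jsonlite,
    yaml,
    RNifti
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
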