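Package: melrisk
Title: Hybrid-Imaging Risk Stratification for Metastatic Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of co-registered whole-body PET/CT and
    PET/MR volumes of metastasized-melanoma patients before systemic
    treatment. Provides NIfTI volume handling, a synthetic multimodal
    phantom-cohort generator, handcrafted lesion features (SULpeak, 42
    percent-isocontour metabolic tumor volume, total lesion glycolysis,
    axial diameters, ADC means, spleen-liver and bone-marrow-liver
    ratios), a survival-marker screening battery (Kaplan-Meier curves,
    Gehan-Breslow-Wilcoxon tests, Welch t-tests, Holm-Bonferroni
    correction), and a multistream squeeze-and-excitation / wide-residual
    convolutional network that stratifies patients into low- and
    high-risk groups under leave-one-patient-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
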