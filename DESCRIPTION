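Package: sodiumq
Title: Quantitative Sodium MRI Simulation and Tissue Sodium Concentration Pipeline
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification pipeline for quantitative sodium
    (23Na) MRI of tumours. Provides a digital-phantom generator built on a
    two-compartment (intracellular/extracellular) sodium model with calibration
    tubes and a surface-coil transmit/receive field; a 3D-cones non-Cartesian
    acquisition simulator with Kaiser-Bessel gridding reconstruction; the
    post-processing chain of squared-subtraction noise-bias correction,
    dual-flip-angle B1 mapping with validity masking and transmit/receive
    inhomogeneity correction; two-point phantom calibration to tissue sodium
    concentration (TSC) and intracellular-weighted sodium (IWS) maps; ROI
    statistics; automated haematoxylin cell counting for tumour cellularity;
    and the cohort statistics (exact Wilcoxon signed-rank, Spearman
    correlation) linking TSC to cellularity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
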