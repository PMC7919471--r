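Package: gdradiomics
Title: Delta Radiomics Response Monitoring with Respiratory-Gated 4D PET
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying clinically relevant FDG-PET radiomic
    changes during radio(chemo)therapy. Provides a synthetic 4D (respiratory
    gated) PET phantom and cohort generator, contrast-oriented semi-automatic
    lesion segmentation (COA), a texture feature bank (first-order, GLCM,
    GLRLM, GLSZM, NGTDM) with wavelet band-pass and equal-probability
    quantization preprocessing variants, a two-criterion feature eligibility
    screen (normality across breathing phases, 3D vs 4D comparability), the
    normalized delta statistic that uses breathing-phase variability as a
    patient-individualized noise floor, and logistic outcome modelling with
    stratified bootstrap performance estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    digest,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
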