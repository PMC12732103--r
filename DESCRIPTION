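Package: neurossl
Title: Multimodal Self-Supervised Representation Learning for Multi-Site
    Neuroimaging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage multimodal self-supervised learning for early
    Alzheimer's disease diagnosis and MCI-to-AD prognosis on multi-site,
    longitudinal MRI/PET cohorts. Stage one pretrains modality-specific 3D
    convolutional encoders with intra-modal and cross-modal InfoNCE,
    longitudinal consistency, BYOL-style regression, and domain-adversarial
    site invariance via gradient reversal. Stage two fine-tunes the encoders
    with missing-aware gated late fusion, class-weighted diagnosis,
    Cox partial-likelihood prognosis, PET-to-MRI distillation, and post-hoc
    temperature calibration. The package also provides intensity
    harmonization (z-score, SUVR, quantile histogram matching, empirical-Bayes
    ComBat), a survival and calibration metrics battery with IPCW and
    bootstrap/DeLong inference, leakage-free subject-level protocols, and a
    synthetic multi-site longitudinal cohort generator with known ground
    truth so the whole pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    RNifti,
    jsonlite,
    survival,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    sva,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
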