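Package: pclr
Title: Patient Contrastive Learning of Electrocardiogram Representations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Patient contrastive pre-training for 12-lead electrocardiograms
    (PCLR). Pairs of ECGs acquired from the same patient at different times are
    treated as positive pairs for a normalized temperature-scaled cross-entropy
    (NT-Xent) loss, so that a residual convolutional encoder learns
    patient-stable representations without any diagnostic labels. The package
    provides the full pipeline: a synthetic multi-visit ECG cohort generator
    with controllable patient-stable morphology and per-visit variability, the
    raw-signal preprocessing contract (microvolt-to-millivolt scaling and
    linear interpolation onto a fixed 4,096-sample grid), patient-pair batch
    sampling, the encoder and projection-head architectures with hand-written
    reverse-mode gradients and an Adam optimizer, a supervised
    train-from-scratch baseline with grid search and early stopping, and the
    ridge-regularized linear-evaluation protocol with bootstrap model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
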