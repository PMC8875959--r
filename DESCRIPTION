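Package: uapsim
Title: Universal Adversarial Perturbations Against Small Image Classifiers
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates and evaluates universal adversarial perturbations
    (UAPs) against small convolutional image classifiers, with an emphasis
    on the cross-domain setting: perturbations crafted from an out-of-domain
    image pool attacking a classifier fine-tuned on a target domain.
    Includes a synthetic two-domain texture image benchmark, small CNNs
    trained either by transfer learning from a source-pool-pretrained
    backbone or from random initialization, iterative non-targeted and
    targeted UAP algorithms with fast-gradient-sign inner steps under L2 or
    L-infinity norm budgets, random-perturbation controls, and an evaluation
    suite (fooling rate, targeted success rate with clean baselines,
    row-normalized confusion matrices, predicted-label composition) plus an
    experiment-grid driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
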