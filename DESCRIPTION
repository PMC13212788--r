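Package: mpuscad
Title: Voxel-Wise Prostate Cancer Detection from Quantitative Multiparametric Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computer-aided detection of clinically significant
    prostate cancer from 3D multiparametric ultrasound, exercisable entirely on
    synthetic phantoms with known ground truth. Implements contrast-enhanced
    ultrasound perfusion quantification (modified local-density-random-walk
    bolus-model fitting, convective-dispersion parameter estimation, neighbour
    similarity analysis, blood-velocity entropy), shear-wave elastography
    processing (Loupas autocorrelator, time-of-flight speed estimation, plane
    stacking), a kriging-based probabilistic histology reference with confidence
    weights, a compact three-branch convolutional network with multilayer
    perceptron head trained under a class-rebalanced two-stage protocol, and
    confidence-weighted receiver-operating-characteristic evaluation with zone
    stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
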