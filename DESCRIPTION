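Package: eitsep
Title: Separation of Heart and Lung Impedance Images in Simulated Thorax EIT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and deep-learning toolkit for separating heart- and
    lung-related conductivity-change images in thorax electrical impedance
    tomography (EIT). Provides a 2-D finite-element forward solver with the
    complete electrode model, adjoint sensitivity (Jacobian) computation,
    one-step regularized difference-image reconstruction, a phantom dataset
    generator producing mixed/lungs-only/heart-only image triplets, a
    shared-encoder dual-decoder ("semi-Siamese") U-Net with a weighted
    multi-task cross-entropy loss implemented natively in C++, a classical
    dual U-Net baseline, and Dice/MAE evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    generics,
    rlang,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
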