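Package: cvmdf
Title: Cervical Vertebral Maturation Staging with Tunable Directional Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated staging of skeletal maturation from lateral
    cephalogram-like radiographs using the cervical vertebral maturation (CVM)
    scheme. Provides a bank of eight zero-DC directional edge filters derived
    from a half-band Lagrange prototype, a compact residual convolutional
    network whose first layer is initialized from (and fine-tunes) that filter
    bank, a channel-features sliding-window detector that localizes the C2-C4
    vertebral column, label-preserving shift/rotation augmentation, a
    stratified split-before-augmentation cross-validation protocol with
    averaged confusion matrices and one-vs-rest ROC/AUC, and a synthetic
    cephalogram generator that encodes the morphological stage definitions so
    the whole pipeline runs end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    png,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
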