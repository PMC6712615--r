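Package: dralnet
Title: Reverse Active Learning and Atrous DenseNets for Noisy-Label
    Histopathology Patch Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-slide pathology images carry one diagnostic label per
    slide, but convolutional classifiers train on small patches cropped
    from the slide.  Propagating the slide label to every patch mislabels
    the normal tissue inside cancerous slides.  'dralnet' implements
    deep-reverse active learning (DRAL): an iterative procedure that
    trains a small CNN (RefineNet), flags training patches whose maximum
    softmax confidence falls below a threshold, removes them with an
    augmentation-group consensus rule, and fine-tunes on the cleaned
    pool.  The package also builds the atrous DenseNet (ADN) classifier
    (dense blocks of dilated convolutions with growth rates 8/16/32 and a
    network-in-network head), sliding-window patch extraction with
    region-of-interest masking and dihedral augmentation, patch-to-slide
    majority-vote fusion, standard accuracy/precision/recall/F-measure
    evaluation, and a synthetic-slide generator with known tumor masks so
    the whole pipeline is testable end-to-end with controllable injected
    label noise.  A compact CPU training engine (im2col/GEMM convolution
    kernels via 'RcppArmadillo') backs both networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
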