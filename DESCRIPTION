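Package: hemseg
Title: Attention-Gated Focus U-Net Segmentation and Volumetry of
    Intracerebral Hemorrhage on CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of intracerebral hemorrhage
    (ICH) on head CT: a synthetic head-CT phantom generator with exact
    analytic lesion volumes, Hounsfield windowing and 512x512 preprocessing,
    a from-scratch 2D attention-gated U-Net with a space-to-depth focus
    encoder branch (trained with RMSprop and a stalled-validation learning
    rate trigger), voxel-count hemorrhage volumetry, an automated Coniglobus
    A*B*C/2 estimator, segmentation metrics (Dice, IoU, sensitivity, PPV,
    95th-percentile Hausdorff distance in mm), and method-agreement
    statistics (intraclass correlation, linear regression). Report-level
    functions return tibbles and chain with the pipe; fitted agreement
    objects have tidy() and glance() methods and results have autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
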