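Package: cochleaCT
Title: Contrast-Enhanced MicroCT Analysis of the Cochlea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of contrast-enhanced micro
    computed tomography (CECT) of the human cochlea: a synthetic cochlear
    phantom generator with exact ground truth (spiral scalae, membranes,
    bony laminae, staining time-course, electrode insertion with
    configurable trauma lesions), a desk-scale parallel-beam tomographic
    simulator with filtered backprojection, metal artifact reduction by
    sinogram projection completion, two-reference grey-value
    normalization and soft-tissue visibility grading, a cylindrical
    cochlear coordinate system with unwrapped angular measurements, 3D
    morphometry (structure volumes, centerline lengths, sphere-fitting
    local thickness maps) and pre/post-insertion electrode trauma
    quantification with Eshraghi grading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    jsonlite,
    yaml,
    tiff,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
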