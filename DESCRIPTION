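Package: stackedellipse
Title: Stacked-Ellipse Semi-Automatic 3-D Ultrasound Segmentation of the Uterus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic segmentation of the uterus on 3-D B-mode ultrasound
    using the stacked-ellipse approach: a single manually contoured mid-sagittal
    slice with four landmark points is expanded into a stack of semi-axial
    elliptical first-guess contours, each contour is deformed towards the
    hypoechoic uterine boundary using a directional edge map and radial peak
    search, regularised by direct least-squares ellipse fitting, and assembled
    into a closed triangulated 3-D surface. Includes the training phase that
    parameterises gold-standard 3-D contours as ellipse stacks and fits the
    population axis model a = m*b + K, evaluation metrics (Dice similarity
    coefficient and mean surface-to-surface distance with cohort median/IQR
    reporting), and a synthetic speckled-phantom generator with exact ground
    truth so the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    EBImage,
    withr,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
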