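Package: lvstrain
Title: Left-Ventricular Myocardial Strain from Cine-MRI by Hierarchical
    Nonrigid Registration with Contour Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks left-ventricular myocardial motion in short-axis cine
    MRI by hierarchical image registration: a global affine stage followed
    by a local cubic B-spline free-form deformation, optimized by gradient
    descent on a sum-of-squared-differences similarity, optionally
    augmented with an endocardial/epicardial contour correspondence
    penalty built on iterative-closest-point matching with curvature as an
    invariant feature.  Dense frame-to-reference displacement fields feed
    Green-Lagrange strain, radial/circumferential strain and strain-rate
    curves aggregated over the AHA 17-segment model.  A synthetic beating
    annulus phantom with analytically known deformation, contours and
    landmarks provides ground truth for validation.  Contours can be
    supplied as CSV or extracted with a gradient-vector-flow snake.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    RNifti,
    tibble,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
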