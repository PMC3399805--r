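Package: fractalvasc
Title: Fractal Complexity Analysis of Cerebral Vasculature Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Quantifies the morphological complexity of two-dimensional
    vessel images by fractal analysis. Implements the box-counting
    dimension, the Minkowski (dilation or "sausage") dimension and the
    generalized Renyi dimension spectrum D_q over q in [0,5], each fitted
    by log-log regression over a scaling range selected automatically with
    a correlation-coefficient threshold. Ships the image operations needed
    to go from an angiographic volume to estimator input (maximum intensity
    projection, exact two-class k-means binarization, Zhang-Suen
    skeletonization, hemisphere splitting), a lattice diffusion-limited
    aggregation simulator and analytic prefractal / multiplicative-cascade
    generators for validation, a synthetic arteriovenous-malformation
    cohort generator, and a study pipeline producing per-hemisphere
    dimension tables, hemisphere contrasts, dimension-versus-physiology
    correlations and Fisher-z sample-size estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    igraph,
    EBImage,
    png,
    tiff,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
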