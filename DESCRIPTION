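Package: slicemapr
Title: Slice-Based CNN Localization of Discriminative Regions in 3D Brain Images
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: A performance-guided two-dimensional slice pipeline for locating
    discriminative candidate regions in three-dimensional structural brain
    images. Plane-specific convolutional binary classifiers are trained on
    sagittal, coronal and axial slices; the best slice per plane (by Matthews
    correlation coefficient) is subjected to occlusion-based attribution, and
    the cross-plane consensus of high-attribution areas defines a candidate
    cubic region of interest that is validated with a lightweight 3D patch
    classifier against a size-matched low-attribution negative control.
    Includes a synthetic phantom generator with a localized signal-injection
    rule, a label-permutation null harness, a dual-threshold selective
    prediction analysis, and an energy-distance two-sample test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
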