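Package: histosift
Title: Scale-Invariant Feature Transform with Bag-of-Features Encoding for
    Histological Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A computer-aided classification pipeline for histological image
    tiles. Detects scale-invariant keypoints as extrema of a
    difference-of-Gaussians scale space, describes each keypoint with a
    128-element gradient-orientation descriptor, encodes images as
    bag-of-features histograms over a k-means codebook (flat or spatial
    pyramid), and classifies them with a one-vs-one support vector machine
    using radial-basis-function or histogram-intersection kernels. Includes
    the matching evaluation protocol (weighted precision, recall and
    F-measure, paired t-tests across trials, majority-vote section labelling
    and patient-level recognition rates), a seeded generator of
    histology-like synthetic textures for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    tiff,
    jpeg,
    kernlab,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
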