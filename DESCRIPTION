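Package: sonoloc
Title: Hierarchical Classification of Liver Ultrasound Scan Locations from
    Segmentation-Derived Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies liver ultrasound images into eleven standardized scan
    locations using features derived from organ and vessel semantic
    segmentation. Implements segmentation-artifact data structures and HDF5
    I/O, per-class geometric shape descriptors (detection tag, centroid, area
    fraction, covariance eigenstructure), global-average-pooled image features,
    a three-channel vessel mask-prediction image for the longitudinal-view
    group, and a two-level hierarchical classifier in which the ambiguous
    right-subcostal group is resolved by a triplet-loss embedding with
    reference-point k-nearest-neighbour voting over a t-SNE grid sample.
    Includes a synthetic segmentation-artifact generator emulating
    class-dependent organ presence, position, size and vessel morphology,
    subject-wise cross-validation splits, and per-class precision/recall/F1
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    digest,
    jsonlite,
    yaml,
    png,
    rhdf5,
    Rtsne,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
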