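Package: inertune
Title: Inertial Tuning Analysis of Neural Activity During Self-Generated
    Head Movements
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-unit recordings combined with
    head-mounted inertial sensing in freely moving animals.  Estimates head
    orientation relative to gravity from gyroscope and accelerometer signals
    with a quaternion complementary filter, decomposes acceleration into
    gravitational and non-gravitational components, predicts movement-driven
    firing rate with a model-free nearest-neighbor resampling estimator,
    fits lag-dependent 3D rotational sensitivity vectors, maps firing rate
    over head-tilt space on the sphere, and classifies units as encoding
    rotations in a head-bound or gravity-anchored reference frame.  Includes
    a synthetic-data generator with planted tuning models so the whole
    pipeline is testable without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
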