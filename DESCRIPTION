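Package: gdlmotion
Title: Key-Frame Rule Classification and Training for Motion-Capture
    Skeleton Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinematic analysis and rule-based action recognition for
    motion-capture skeleton streams, in the Gesture Description Language
    (GDL) tradition.  Per-frame features (joint-angle and general vector
    algebra expressions) are evaluated from 3D joint positions; actions
    are recognised as time-restricted ordered sequences of rule-defined
    key frames held in a bounded memory stack; key-frame rule sets can be
    trained automatically from exemplar recordings by k-means clustering
    in feature space (R-GDL).  Includes a plain-text frame-stream format,
    BVH import with forward kinematics, a synthetic labelled-motion
    generator for validation, and command-line entry points for feature
    extraction, classification, training, simulation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
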