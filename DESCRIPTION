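Package: patchtrack
Title: Kinematic Analysis of Root Growth by Image Patch Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures plant root growth in kinematic terms from time-lapse
    micrographs. Many small circular image patches seeded along the root
    midline are followed from frame to frame with an iterative affine
    intensity-constancy solver that recovers each patch's translation,
    stretch and rotation. The resulting cloud of (position, velocity)
    samples, referenced to the quiescent center, is fitted with the
    four-parameter flexible logistic velocity profile of Morris and Silk,
    whose derivative is the relative elemental growth rate (REGR) profile.
    Four kinematic traits of the elongation zone are extracted: maximum
    REGR, its axial position, elongation-zone length and average growth
    rate. A synthetic time-lapse generator with exact ground-truth
    kinematics supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    EBImage,
    grDevices,
    graphics,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
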