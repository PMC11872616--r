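Package: sonoKinetics
Title: Video Colorimetry of Ultrasound-Assisted Extraction Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies extraction kinetics from experiment videos by
    region-of-interest colorimetry. Frames are reduced to mean RGB values
    inside a circular mask, normalized to the intact-sample reference
    color, and fitted phase-wise by linear regression to report extraction
    speeds in percent per second for a conventional (water-only) phase and
    an ultrasound-assisted phase, together with the enhancement ratio.
    Includes a synthetic video generator with known ground-truth rates so
    the whole pipeline can be validated without experimental footage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
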