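Package: fundusPitch
Title: Generic Pixel-Pitch Calibration for Fundus Cameras
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical calibration of the pixel pitch (micrometres per
    pixel) of retinal fundus photographs without access to the camera or
    its specifications. The package detects the circular region of
    interest (ROI) of a 45-degree fundus photograph with a circular Hough
    transform, measures the optic-disc diameter through polar-coordinate
    edge detection and a farthest-pair circumscribed-circle fit, pools
    published optic-disc diameters into an anatomical prior with a
    random-effects meta-analysis, and converts the ROI-to-disc diameter
    ratio into a per-image pixel pitch with propagated uncertainty using
    a reduced-eye optical model. A seeded synthetic fundus-image
    generator with ground truth supports validation end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    metafor
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: Visualization, Preprocessing, BiomedicalInformatics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
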