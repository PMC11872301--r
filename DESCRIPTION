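Package: achr
Title: Alveolar Crestal Height Measurement from Bitewing Radiograph
    Landmarks and Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline that turns landmark detections
    (alveolar bone crestal level, cemento-enamel junction) and binary
    segmentation masks from bitewing radiographs into per-tooth-site
    alveolar crestal height (ACH) measurements in millimeters and
    severe/non-severe periodontal bone-loss calls. Includes dual-detector
    landmark fusion by greedy non-maximum suppression, arch partitioning by
    a best-fit line through bone-crest pixels, per-arch polynomial curve
    fitting with a tooth-outline crossing gate, pixel-to-millimeter
    calibration, a synthetic bitewing phantom generator with exact ground
    truth, a noisy oracle detector for end-to-end testing without clinical
    images, and an evaluation suite (per-image and pooled severity accuracy,
    severe-class sensitivity, intraclass correlation ICC(A,1)).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
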