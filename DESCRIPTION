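Package: focidose
Title: Automated gamma-H2AX Focus Scoring and Radiation Biodosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for gamma-H2AX focus based radiation
    biodosimetry on confocal fluorescence microscopy. Simulates
    three-channel (DAPI nucleus / gamma-H2AX foci / CD45 surface) z-stack
    images of mononuclear cells with dose-dependent focus counts and exact
    ground truth; applies the standard intensity-normalisation chain
    (histogram matching, median and Gaussian filtering); runs a two-stage
    detection workflow (mononuclear-cell localisation and cropping, then
    green-channel spot detection) with a pluggable detector contract and a
    deterministic classical reference backend; evaluates detections with
    bounding-box precision/recall/F1; fits linear dose-response calibration
    curves, inverts them for dose estimation with mean-absolute-difference
    reporting; and computes rater-agreement statistics (two-way
    random-effects intraclass correlation and Bland-Altman limits of
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
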