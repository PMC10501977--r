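Package: kneeqc
Title: Automated Positioning Quality Control for Knee Radiographs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automatic positioning quality control for anteroposterior
    (AP) and lateral (LAT) knee radiographs. Nine anatomical key points on the
    fibula, tibia and femur are localized by multiresolution heatmap
    regression and converted by planar geometry into three clinical
    positioning criteria: the AP and LAT fibular-head/tibia overlap ratios and
    the LAT knee flexion angle. The package provides the geometric criterion
    calculator, a Gaussian heatmap encoder/decoder with automatic AP/LAT view
    identification, a trainable high-resolution multibranch keypoint detector,
    an evaluation stack (object keypoint similarity with mAP/mAR, ICC(2,1)
    agreement analysis, deviation statistics, t tests), and a seeded synthetic
    knee-phantom generator with exact ground-truth key points for end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
biocViews: Software, BiomedicalInformatics, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
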