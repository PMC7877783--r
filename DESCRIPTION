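Package: octmargin
Title: Multimodal Optical Assessment of Breast Surgical Margins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for intraoperative breast
    surgical margin assessment combining fluorescence guidance, reflectance
    confocal microscopy (RCM) labelled training regions and optical coherence
    tomography (OCT) texture segmentation. Provides a seeded synthetic
    specimen phantom generator (speckled, attenuating OCT volumes with
    class-distinct tissue textures, enzyme-activated fluorescence and
    co-registered ground truth), spectral-domain A-line simulation with
    theoretical axial resolution, roughness/waviness texture decomposition
    with sliding-window standard deviation and Prewitt slope features,
    top/bottom tissue surface segmentation, strip planning and
    cross-correlation mosaic stitching, quenched-probe activation kinetics,
    threshold-based tissue classification trained from labelled regions,
    depth-resolved margin projection, and specimen-level evaluation with
    confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
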