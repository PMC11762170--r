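Package: stereoAVS
Title: Stereo-Orientation Selectivity with a Hubel-Wiesel Cell Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An artificial visual system for recognizing the 3D orientation of
    structures in binary voxel volumes, built as a Hubel-Wiesel cascade of
    depth-selective cells, simple stereo-orientation selective cells (sharp
    sigmoid detectors for the 13 canonical line directions through a 3x3x3
    neighborhood), and complex cells that pool same-orientation responses
    across the volume. Includes seeded generators for the standard
    physiological stimulus protocols (drifting gratings, random-dot volumes
    with embedded motion fragments, oriented line/bar datasets with background
    noise), an orientation-based positive/negative feature separation filter
    for point-cloud denoising with random and farthest-point subsampling, an
    evaluation harness (accuracy, confusion, activation traces), and readers
    and writers for dense volumes, coordinate tables, ascii PLY and XYZ point
    clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
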