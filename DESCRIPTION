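Package: agavecount
Title: Counting Agave Plants in Segmented UAV Imagery with Mathematical
    Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Counts blue agave (Agave tequilana Weber) plants in
    pre-segmented crop-layer images derived from unmanned aerial vehicle
    orthomosaics. Implements a binary mathematical-morphology pipeline:
    luminance conversion and binarization of the segmented layer,
    clean/fill preprocessing, opening-closing object separation with a
    3x3 square structuring element, and an iterative erosion procedure
    with a diamond structuring element that harvests connected
    components below an equivalent-diameter threshold until the field is
    exhausted. Includes producer's/user's accuracy, recall and average
    accuracy metrics with greedy centroid matching against expert ground
    truth, a seedable synthetic field generator (row crops, overlap,
    weeds, holes, illumination dropouts) for validation without flight
    data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
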