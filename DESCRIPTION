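Package: optopore
Title: Automated Laser-Optoporation Targeting, Scan Scheduling and
    Outcome Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hardware-free implementation of a computer-automated
    laser-optoporation workflow for adherent cell monolayers:
    bright-field cell targeting by rake-line edge detection with
    hysteresis, greedy removal of near-duplicate targets, serpentine
    (meander) mosaic planning over microscope fields of view with a
    stage/shutter/camera timing model and focus-plane height
    correction, a closed control loop run against virtual hardware
    with an auditable event log, and fluorescence-based outcome
    classification (intact, optoporated-alive, dead) from DAPI,
    ethidium bromide and calcein channels, including extended
    h-maxima nucleus segmentation and the dead/optoporated summary
    ratios. A synthetic-scene generator with per-cell ground truth
    makes every stage testable without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
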