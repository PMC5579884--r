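Package: labweed
Title: Plant Recognition and Spot-Spraying Decisions from True-Color CIE-Lab Point Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for recognizing small plants (weeds and crops) from
    point-spectral true-color readings in the CIE-Lab color space, as used by
    sensor-valve-nozzle units for site-specific herbicide application.
    Provides color-difference detectors (Delta-E and per-channel deltas with
    thresholds), a statistical existence rule based on background and object
    noise, a minimum-coverage model predicting the smallest detectable plant
    fraction of the measuring spot per background and green tone, a
    direction-matching multistage green-tone classifier, packaged color
    databases of anthropogenic and natural backgrounds and reference greens,
    a seeded synthetic sensor-transect simulator with ground-truth
    annotation, and a command-line interface binding calibration, detection,
    coverage tables and simulation together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
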