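Package: templacal
Title: Calibration-Error Propagation in Digital Templating for Total Hip Arthroplasty
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deterministic model of how radiographic calibration errors
    propagate into acetabular component size selection during preoperative
    digital templating for total hip arthroplasty. Projects true component
    diameters through a percent magnification error, snaps the projection to
    a discrete implant catalog, and sweeps error-by-size grids into
    color-coded deviation matrices with CSV/HTML/plot export, forward and
    inverse size lookups, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
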