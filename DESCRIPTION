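Package: sma
Title: Automated Muscle Architecture Measurement from B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automated measurement of pennation angle, fascicle
    length and muscle thickness from longitudinal B-mode ultrasound
    scans of pennate muscle. The pipeline detects the ultrasound field
    of view, segments the superficial and deep aponeuroses using
    Hessian-based tubeness filtering and frequency-domain directional
    masking, measures the dominant fascicle orientation with the
    gradient structure tensor inside overlapping regions of interest,
    and combines the results into architecture parameters. Includes a
    synthetic ultrasound phantom generator with analytic ground truth
    for validation, a Bland-Altman agreement helper, batch processing,
    overlay rendering and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
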