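Package: bbcsim
Title: Ballistic Droplet Blocking: Stain-Image Quantification, Transport
    Simulation, and Cloth-Model Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how well porous fabrics block large ("ballistic")
    respiratory droplets. Computes the Ballistic Blocking Capacity (BBC)
    statistic from binarized stain-pattern scans, simulates droplet
    transport under gravity and Stokes drag through a porous barrier
    characterized by a tunneling probability and a deceleration factor,
    and calibrates those two parameters against blocking observations by
    weighted least squares. Includes a synthetic scanner-image generator
    with known ground truth so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
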