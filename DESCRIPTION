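Package: microvel
Title: Spatial-Frequency Velocimetry and Transit-Time Mapping for
    Microvascular Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates mean red blood cell (RBC) speed in single
    microvessels from two-photon line-scan (kymograph) images by locating
    the dominant orientation of the two-dimensional power spectrum.
    Includes Radon-transform and singular-value-decomposition comparator
    estimators, frequency-domain bandpass filtering, seeded synthetic
    scene generators with exact ground truth, and an arteriovenous
    transit time (AVTT) pipeline that maps per-pixel dye appearance times
    in bolus time-lapse stacks and summarises arterial and venous
    segments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
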