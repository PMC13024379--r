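Package: beadmetrics
Title: Quantification of Magnetic-Bead Distribution and ECL Photodetector Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of magnetic-bead deposition on the working
    electrode of an electrochemiluminescence immunoassay (ECLIA) cell, and
    processing of the photodetector voltage output. Implements red-green channel
    compositing, percentile contrast stretching, labeled-sample threshold
    calibration and binarization, area-fraction coverage, a 3x3 grid uniformity
    statistic, axial coverage profiling and pre/post air-gap profile deviation;
    inverse-logarithmic reconstruction of the photomultiplier current from the
    log-amplifier voltage trace and background-corrected charge integration over
    adjacent 0.4-s windows; calibration linearity, coefficient of variation,
    method comparison and fluidic-condition selection statistics; and seeded
    synthetic generators for bead-field micrographs, air-gap defects and
    voltage-time traces so that every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
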