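Package: perivasc
Title: Quantification of Perivascular Tracer Accumulation from Two-Channel
    Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies perivascular accumulation of a fluorescent tracer
    around blood vessels in two-channel (tracer + lumen dye) fluorescence
    time-lapse images.  The core is a line-profile intensity statistic:
    cross-vessel profiles are aligned to the lumen edge detected on the
    lumen-dye channel at half maximum, and the mean tracer intensity in the
    first 3 micrometres outside the lumen is contrasted against the next
    7 micrometres to call a vessel tracer-positive.  Includes a synthetic
    two-photon-style image simulator with known ground truth (vessel
    geometry, point-source diffusion background, time-varying perivascular
    rings, photon and read noise), vessel diameter and time-course metrics,
    distance-to-source stratification, vessel-wall morphometry on labelled
    masks, and the group-level statistics (Welch/Student t, two-way ANOVA
    with Tukey correction) used for such experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
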