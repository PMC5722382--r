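Package: leafknot
Title: Contour Capture of Leaves with Touching and Overlapping Lobes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Captures the closed, possibly self-intersecting outline of
    leaves whose lobes touch or overlap, from transilluminated grayscale
    images. Implements two-level segmentation (maximum-entropy and
    intermeans thresholds combined by XOR), boundary tracing of every
    blade, overlap and closed-sinus region, localization of cross and
    touch points between adjacent contours, an orientation-aware splice
    algorithm that concatenates all contours into a single closed ring,
    and elliptic Fourier analysis of the result with stepwise inverse
    reconstruction. Ships a synthetic transilluminated-leaf generator
    with analytic ground truth for end-to-end testing, contour cut/repair
    utilities, ImageJ-compatible XY coordinate import/export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    optparse,
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
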