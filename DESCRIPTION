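Package: forcemap
Title: Automated Analysis of AFM Force-Volume Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automated processing of atomic force microscopy (AFM)
    force-volume images recorded on soft biological samples such as
    bacteria.  Approach and retraction force curves are segmented by a
    greedy change-point algorithm with piecewise polynomial smoothing;
    approach curves are then fitted to an electrostatic double-layer +
    Hertz (conical tip) + Hooke piecewise model yielding the electrostatic
    prefactor, Debye length, Young modulus and cell spring constant, while
    retraction curves are decomposed into pulling events fitted to the
    Freely Jointed Chain model, yielding contour and Kuhn lengths and
    rupture statistics.  Per-pixel parameter maps, pooled histograms and a
    synthetic force-curve generator with known ground truth are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
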