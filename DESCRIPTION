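Package: midgut4d
Title: Quantitative Analysis of 4D Live-Imaging Movies of the Drosophila Adult Midgut
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of long-term volumetric
    time-lapse movies of the adult Drosophila midgut epithelium. Implements
    cell typing from combinatorial nuclear reporters (channel-mask arithmetic
    and a nuclear-size filter), nucleus segmentation and frame-to-frame track
    linking, extrusion-ring morphometry with ratchet-pulse decomposition,
    stem-cell division orientation in three reference frames and a mitotic
    index, and Notch-activation fate dynamics based on a normalized GFP:RFP
    reporter ratio with bimodal threshold estimation, transition calling and
    sibling-contact inference. A synthetic-movie generator with full ground
    truth stands in for raw microscopy data so that every analysis stage is
    testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
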