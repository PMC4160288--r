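Package: spinemorph
Title: Rapid Dendritic Spine Morphometry from Serial-Section Trace Exports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies and classifies dendritic spines measured on
    Golgi-Cox stained material with the RECONSTRUCT serial-section tracing
    tool. Reads the comma-separated Trace List (spine head widths, 2D) and
    Z-Trace List (3D contour lengths) exports, decodes the trace-naming
    conventions used to mark dendrites and spines, pairs widths with
    lengths, computes length-to-width ratios, and assigns each protrusion
    one of six morphological types (branched, filopodium, mushroom, long
    thin, thin, stubby) with a hierarchical threshold rule. Per-dendrite
    summaries (protrusion density per micron, mean width, length and
    length-to-width ratio, type fractions) and two-group Student's t
    comparisons are provided, together with a seeded synthetic-data
    generator that emits the same export formats with known ground truth
    so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
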