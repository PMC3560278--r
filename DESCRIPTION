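Package: colonyscatter
Title: Label-Free Scoring of Stem-Cell Colony Quality from Laser
    Forward-Scatter Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for optical forward-scatter
    scoring of human embryonic stem cell (hESC) colonies. Generates
    three-dimensional colony phantoms with class-specific morphology
    (uniform flat "good" colonies versus lumpy, irregular-edged "bad"
    colonies), simulates laser forward scattering through them with a
    thin-phase-object model and band-limited angular-spectrum
    propagation, extracts rotation-invariant pseudo-Zernike moment
    magnitudes from the scatter patterns, ranks and selects features by
    Fisher's criterion, and classifies colony quality with a support
    vector machine. Companion morphometry tools estimate colony height
    from confocal-style z-stacks and quantify pluripotency as the
    Oct-4/DAPI integrated fluorescence ratio, with two-sample t-test
    comparisons between quality classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
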