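Package: gcmotility
Title: Quantification of Growth-Cone Lamellipodia and Filopodia Motility and Force
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the motility of neuronal growth-cone
    lamellipodia and filopodia from phase-contrast Z-stack time-lapse
    imaging, and the forces they exert on optically trapped beads.
    Implements kymograph-based measurement of protrusion/retraction period,
    persistence length and retrograde flow rate; defocus-based fractional
    height analysis of vertical lamellipodial motion; optical-trap force
    traces with nanopositioner-feedback compensation and classification of
    push/retraction events; and filopodium tip tracking. A synthetic-data
    generator produces image stacks and bead traces with known ground truth
    so that every estimator is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
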