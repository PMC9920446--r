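Package: mitchain
Title: Separated Inversion Chain for Planar Magnetic Induction Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and separated inverse reconstruction for planar
    magnetic induction tomography (MIT) with an undulating excitation coil.
    Implements a weak-coupling eddy-current forward model on a resistor-network
    discretisation of a 2D conductivity sheet, receiver signal synthesis by the
    reciprocity theorem, and the four decoupled inverse stages: carrier-based
    signal splitting, Landweber reconstruction of magnetic dipole moments,
    discrete curl from moments to eddy currents, and iterative nonlinear
    conductivity correction.  Includes synthetic phantom generation and noise
    injection so every stage can be exercised end-to-end without measurement
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
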