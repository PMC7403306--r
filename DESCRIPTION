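Package: cavrheo
Title: Laser Cavitation Rheology of Soft Hydrogels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward simulation of laser-generated cavitation bubble dynamics in
    a Neo-Hookean viscoelastic medium with material failure, and inverse
    recovery of the elastic modulus and failure strains of soft hydrogels from
    bubble radius-time measurements. Provides the phase-switched constitutive
    relations (intact, plastic, recovery), a full growth/collapse cycle solver
    with event detection, bounded Levenberg-Marquardt fitting of the maximum
    radius, elastic modulus and radial failure strain, Green-Lagrange
    finite-strain fields around the bubble, polymer mesh-size estimation,
    k-means bubble image segmentation with equivalent radii, and a
    synthetic-data generator emulating time-resolved photography, plus a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
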