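Package: icrsplan
Title: Neural-Network-Guided Planning of Intracorneal Ring Segment
    Implantation in Keratoconus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning intracorneal ring segment (ICRS) surgery in
    keratoconic eyes from anterior corneal elevation maps. Fits Zernike
    polynomial expansions (ANSI/OSA convention, radial order up to 7) to
    gridded elevation data, converts elevation to corneal wavefront,
    computes point-spread functions and Strehl ratios by Fourier optics,
    and ranks every candidate one- or two-segment implant configuration by
    the Strehl ratio of the post-operative cornea predicted by a
    feedforward neural network trained with backpropagation and momentum
    on successful surgical cases. Includes clinical metrics (LogMAR
    conversion, visual-limitation grading, simulated keratometry, the
    surgical success filter, a keratoconus progression criterion) and a
    synthetic keratoconic-cornea generator with a mechanistic ring-effect
    model so the full pipeline can be trained and validated without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
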