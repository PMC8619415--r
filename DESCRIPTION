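Package: ogjfet
Title: Open-Gate JFET Biosensor Device and Interface Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computational model of an open-gate junction
    field-effect transistor (OG-JFET) biosensor. Implements the site-binding
    electrochemistry of a native-oxide sensing surface (pH to surface
    potential and surface charge density), a one-dimensional
    drift-diffusion-Poisson solver with Scharfetter-Gummel discretization and
    Shockley-Read-Hall recombination for the vertical p-n structure, a
    quasi-2-D gradual-channel coupling that turns surface charge and bias
    into drain-source current families, and the characterization analyses
    used for such sensors: constant-current reference-voltage sensitivity,
    current sensitivity versus bias, step-response analysis of time traces,
    and Debye screening-length estimation. A synthetic-data module generates
    JFET-like current-voltage families with planted analyte sensitivities so
    the full extraction pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
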