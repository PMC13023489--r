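Package: dcbsim
Title: Paclitaxel Transfer and Retention Modelling for Drug-Coated Balloon Angioplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale transport model of paclitaxel delivery from a
    drug-coated angioplasty balloon into a stenotic vessel wall. Builds
    parametric post-dilation axisymmetric geometries, solves the transient
    diffusion equation with an implicit finite-volume scheme, calibrates the
    balloon-to-wall transfer coefficient against in vitro absorption
    measurements, simulates post-withdrawal free diffusion under a prescribed
    luminal mass-loss schedule, and selects the balloon dilation time that
    keeps tissue concentration below the toxic threshold at 24 hours while
    maximising the time above the effective threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
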