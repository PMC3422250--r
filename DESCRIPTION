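Package: dgnmaize
Title: Dynamic Gene Network Model of the Maize Floral Transition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and calibrates a four-gene dynamic gene network (DGN)
    model of the floral transition in maize. A logic-gated linear ordinary
    differential equation drives scaled ZMM4 mRNA abundance from the binary
    allele states of ID1, DLF1 and VGT1 (plus a ZMM4-overexpression transgene
    flag); the time at which the trajectory reaches a threshold predicts days
    to tassel initiation (DTI). Includes forward-Euler simulation with an
    analytic closed-form oracle, Nelder-Mead estimation of the five model
    coefficients from scaled expression time series and observed DTI, a
    seeded synthetic-data generator for parameter-recovery studies, and an
    evaluation step regressing total leaf number (TLN) on predicted DTI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
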