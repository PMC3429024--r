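Package: rbcatp
Title: Oxygen-Dependent Erythrocyte ATP Release and Capillary Network
    Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dynamic kinetic model of the low-oxygen-induced ATP release
    pathway of the human erythrocyte (Gi protein activation, cAMP, PKA and
    CFTR, with PDE3-mediated cAMP hydrolysis), coupled to a steady-state
    solver for plasma ATP transport in capillary networks with endothelial
    ATP degradation and a conducted-vasodilation signal. Includes
    perturbation scenarios for elevated insulin (increased PDE3 activity,
    halved network release) and reduced Gi expression, a reproducible
    synthetic capillary network generator with the statistical structure of
    a rat extensor digitorum longus muscle network, a plain-text network
    exchange format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
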