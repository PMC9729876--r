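Package: dsdwta
Title: Winner-Take-All DNA Strand-Displacement Circuits from Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end in-silico pipeline that turns miRNA expression
    cohorts into molecular classifiers. It selects differential-expression
    biomarkers, summarises co-expression structure with a weighted network
    (soft thresholding, topological overlap, module eigengenes, hub genes),
    compiles the selected markers and one sample's FPKM values into a
    two-layer toehold-mediated strand-displacement circuit with a
    winner-take-all readout, simulates the circuit's mass-action kinetics
    (deterministic ODE and Gillespie stochastic simulation), and calls each
    sample tumor, normal or indeterminate from the endpoint FAM/ROX
    fluorophore-channel signals. A synthetic-cohort generator with planted
    markers, latent-factor co-expression modules and derived clinical traits
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
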