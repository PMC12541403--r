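Package: redoxfilm
Title: Reaction-Diffusion Modelling and Trace Analysis for Hydrogenase
    Viologen Redox Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mediated electron transfer in enzyme-loaded viologen
    redox films on electrodes: a one-dimensional reaction-diffusion model of
    electron hopping, H2 and O2 transport, bidirectional enzyme catalysis and
    potential- and O2-driven enzyme inactivation, with steady-state and
    transient solvers. Includes electrochemical potential arithmetic
    (SHE/RHE scales, H+/H2 equilibrium, Nernst potentials), cyclic
    voltammetry and chronoamperometry simulation and analysis (mediator
    midpoint potential extraction, normalization, catalytic plateau
    detection), residual-activity analysis across repeated air exposures,
    and seeded synthetic-trace generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
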