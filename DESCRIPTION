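Package: haptk
Title: Spatially-Resolved Pharmacokinetics and Bystander Modelling for
    Hypoxia-Activated Prodrugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatially-resolved pharmacokinetic/pharmacodynamic
    (SR-PK/PD) analysis of hypoxia-activated prodrugs and their diffusible
    cytotoxic metabolites, modelled on the nitrogen mustard prodrug CP-506.
    Provides a two-compartment cellular PK model for monolayer uptake and
    oxygen-gated metabolism with a sequential (fix-then-fit) estimation
    protocol; a one-dimensional reaction-diffusion model of drug flux across
    stirred donor / multicellular layer / support membrane / receiver
    diffusion chambers with staged estimation of membrane and tissue
    diffusivities, layer thickness and the metabolic scaling factor; a
    lattice agent-based spheroid model (growth, oxygen, necrosis, drug
    gradients, clonogenic kill) with a fast spherically-symmetric continuum
    surrogate; four-parameter logistic dose-response utilities; seeded
    synthetic-data generators for every assay; and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
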