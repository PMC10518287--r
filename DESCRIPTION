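Package: kroghcpa
Title: Krogh-Cylinder Transport and Toxicity Modelling of Cryoprotectant
    Loading in Whole Organs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation, parameter estimation and protocol
    optimization for cryoprotective agent (CPA) perfusion loading of whole
    organs. The vasculature is represented by parallel Krogh cylinder
    units; water and CPA exchange across the capillary membrane follows
    the Kedem-Katchalsky flux equations, vascular resistance follows
    Poiseuille's law, and cumulative chemical toxicity is scored by a
    power-law toxicity cost function. Includes an organ-level Boyle van't
    Hoff analysis of stepped-osmolarity perfusion data, least-squares
    estimation of membrane transport parameters from resistance
    transients, slice-viability toxicity calibration, constrained grid
    optimization of ramp-hold-step loading protocols, and seeded synthetic
    data generators emulating the perfusion and slice experiments.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
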