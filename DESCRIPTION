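Package: luxkin
Title: Single-Turnover Kinetics of the Bacterial Bioluminescent Reaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the kinetic analysis of the single-turnover reaction
    catalyzed by bacterial luciferase. Simulates the multi-intermediate
    reaction scheme as a mass-action ordinary differential equation system,
    globally fits the elementary rate constants (flavin binding, oxygen
    binding, aldehyde binding/dissociation and the catalytic constant) to
    sets of flash-like bioluminescence intensity curves recorded at several
    aldehyde concentrations, extracts empirical curve parameters (peak
    intensity, decay constant, initial velocity, quantum yield), estimates
    flavin autoxidation and peroxyflavin dark-decay constants from
    absorbance traces, analyses power-law viscosity dependencies of rate
    constants, evaluates Norrish water activity of cosolvent solutions,
    and computes fluorescence spectral gravity centers. Includes seeded
    synthetic-data generators with known ground truth for validating
    every stage of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
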