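Package: redoxsim
Title: Kinetic Simulation of Oxidative-Stress Pathways and Their Modulation
    by Dietary Phytonutrients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and integrates kinetic reaction-network models of
    cellular oxidative stress: a reactive-oxygen-species (ROS) production
    network (NADPH-oxidase superoxide source, superoxide dismutase,
    catalase, the glutathione/glutathione-peroxidase cycle, Fenton
    chemistry and lipid peroxidation) and an Nrf2/Keap1/ARE
    antioxidant-enzyme production network. Provides a typed
    reaction-network container with mass-action, Michaelis-Menten, Hill
    and constant-flux rate laws, stoichiometry and conserved-moiety
    analysis, SBML Level 3 import/export, stiff ODE integration with
    steady-state detection, a phytonutrient dosing layer (six compounds
    with ROS-scavenging and Nrf2-axis mechanisms, Cmax-based dose-to-serum
    mapping), deterministic calibration of enzyme baselines and compound
    effect constants, and an experiment layer for control, dose-response
    and combination simulation campaigns over a seven-day horizon.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
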