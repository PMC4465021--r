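Package: milkwarm
Title: Conjugate Heat Transfer Simulation of Bottle Warming in a Hot
    Water Bath
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transient finite-volume simulation of warming refrigerated
    milk in a baby bottle immersed in a hot water bath.  The model couples
    heat conduction in the bottle and nipple plastic with buoyancy-driven
    (Boussinesq) natural convection in the milk, the headspace air and the
    surrounding bath water on a structured axisymmetric mesh.  Includes
    bottle presets, a randomized scenario generator, mass-weighted
    temperature and overheated-volume metrics, Stokes stream functions,
    closed-form verification oracles (transient slab conduction, lumped
    capacitance), CSV/VTK output and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
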