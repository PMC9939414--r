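Package: coilflow
Title: Pulsatile Hemodynamics of Coiled Bilobed Cerebral Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile, non-Newtonian (regularized Casson,
    hematocrit-dependent yield stress) incompressible blood flow through a
    parametric two-dimensional bilobed (double-dome) aneurysm geometry on a
    staggered Cartesian grid, with the vessel wall imposed by Brinkman
    volume penalization and endovascular coil packing modelled as a Darcy
    porous momentum sink (Kozeny-Carman permeability). Post-processes wall
    shear stress, oscillatory shear index, time-averaged wall shear stress,
    wall pressure and neck-plane inflow metrics at the four cardiac phase
    instants, and orchestrates hematocrit-by-porosity comparison studies
    with a grid-convergence harness and analytic benchmarks (Poiseuille,
    Womersley, Casson channel, Darcy).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
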