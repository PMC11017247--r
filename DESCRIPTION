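Package: rwail
Title: The rWAIL Water Potential with a Desk-Scale Simulation and Analysis Stack
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the rWAIL four-site water potential (flexible and
    rigid ensemble-geometry variants) with analytic forces, virtual-site
    force redistribution and Ewald electrostatics; a minimal periodic
    molecular-dynamics engine (NVE/NVT/NPT, slab geometry, rigid
    constraints, long-range corrections); estimators for radial
    distribution functions, isothermal compressibility, heat capacity,
    heat of vaporization, dielectric constant, self-diffusion and surface
    tension; and the critical-phenomena analysis machinery: Wegner
    coexistence fits, singular-diameter critical density, Antoine vapor
    pressure, the extended IAPWS surface-tension correlation with an
    emergence temperature, liquid-liquid critical point localization on
    (T,P) grids, and a three-phase melting-point protocol driver.
    Deterministic fixture generators (water boxes, slabs, proton-disordered
    ice Ih, synthetic time series and curves with known ground truth) and
    Gromacs-compatible topology/structure input and output are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    lhs,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
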