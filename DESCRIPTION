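Package: phacotherm
Title: Anterior-Chamber Thermo-Fluid Simulation and Endothelial Outcome
    Statistics for Phacoemulsification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional finite-element model of heat and fluid transport
    in the anterior chamber of the eye during phacoemulsification.  The model
    couples incompressible laminar flow under the Boussinesq buoyancy
    approximation with advective-diffusive heat transport, includes a Brinkman
    porous block for the trabecular meshwork with a Schlemm's canal outlet,
    and drives a five-second boundary heat impulse representing the
    ultrasound probe tip at several total powers for three filling fluids
    (aqueous humor, balanced salt solution, and a high-viscosity
    viscoelastic).  A companion biostatistics stage generates synthetic
    longitudinal patient cohorts (endothelial cell density, intraocular
    pressure, visual acuity, morphometry) and implements the corresponding
    endpoint computations: percent endothelial cell loss, morphometry
    summaries, normality screening, two-group and longitudinal comparisons,
    and pressure-peak counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
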