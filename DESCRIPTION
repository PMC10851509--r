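Package: retentoKin
Title: Pirt Kinetics and Near-Zero-Growth Retentostat Modelling for Protein-Producing Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of maintenance-energy (Pirt) kinetic parameters from
    glucose-limited chemostat data by moving-window linear regression, forward
    simulation of retentostat cultures approaching zero specific growth rate
    with recombinant-protein formation and perfusion washout, non-linear
    least-squares regression of retentostat biomass accumulation profiles, and
    piecewise product mass-balance estimation of specific productivity.
    Includes seed-deterministic synthetic-data generators so the whole
    pipeline is testable without bioreactor data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
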