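Package: phasekin
Title: Nucleation Kinetics of Biomolecular Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the nucleation kinetics of liquid-liquid
    phase separation of low-complexity protein domains. Provides scattering
    models for disordered monomers (Debye and generalized-polymer form
    factors), Guinier analysis, and a low-angle assembly metric for
    time-resolved SAXS; a stochastic cluster birth-death simulator built on
    classical nucleation theory with a Gibbs-Thomson rate kernel; fitting of
    collapse-and-growth chain dimension kinetics and scaled-Weibull
    nucleation kinetics with barrier-scaling extrapolation across quench
    depths; equilibrium models for binodals, self-association sedimentation
    isotherms with hydrodynamic scaling and nonideality, Gilbert asymptotic
    boundary shapes, and FCS correlation fits; and seeded synthetic-data
    generators that emulate each measurement so the whole pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
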