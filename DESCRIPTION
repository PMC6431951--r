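Package: polyknot
Title: Knot Interactions on Stretched Semiflexible Polymers
Version: 0.1.0
Authors@R:
    person("polyknot", "developers", email = "polyknot@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained bead-spring modelling of semiflexible polymer
    chains under tension carrying multiple knots. Provides an underdamped
    Langevin integrator for the Kremer-Grest chain (WCA excluded volume,
    FENE bonds, cosine bending, confining walls), open-chain knot
    localization via minimally interfering closure and Alexander
    determinants at t = -1 and t = -2, chirality assignment from signed
    crossings, knot separation and orientation order parameters,
    free-energy profiles with exact sliding-segment entropy subtraction,
    and the elastic model for the equilibrium knot size. All fixtures are
    generated synthetically; XYZ and LAMMPS dump trajectories are read and
    written.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
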