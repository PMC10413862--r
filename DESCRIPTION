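Package: septop
Title: Separated-Topologies Relative Binding Free Energy Setup and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for setting up and analysing separated-topologies (SepTop)
    relative binding free energy calculations. Selects Boresch-style
    orientational restraint reference atoms from structures and equilibration
    trajectories, builds the dual-ligand alchemical GROMACS topologies for the
    binding-site thermodynamic cycle (including epsilon-scaled replica-exchange
    intermediates and a charge-preserving solvent protocol), generates
    lambda-window schedules and run-parameter files, estimates free energies
    from cross-evaluated reduced potentials with MBAR, applies the analytic
    standard-state restraint-release correction, and diagnoses free-energy
    networks through cycle closure, edge voting, hysteresis and a
    maximum-likelihood solve of absolute binding free energies. Synthetic
    fixture generators provide fully controlled inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
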