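Package: polydroplet
Title: Polymer Conformations at Phase-Separated Droplet Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained Langevin-dynamics simulation of implicit-solvent
    bead-spring polymers (hydropathy-scaled Lennard-Jones interactions with
    optional screened electrostatics) together with an analysis pipeline for
    phase-separated droplets: largest-cluster droplet detection under periodic
    boundaries, radial concentration profiles with hyperbolic-tangent interface
    fits, chain- and segment-level radius-of-gyration statistics, interchain
    and intrachain contact profiles, and segment orientation angles relative to
    the droplet surface. Includes a synthetic-droplet generator with planted
    density, compactness, end-enrichment and orientation structure for
    parameter-recovery testing, plus readers and writers for XYZ and
    LAMMPS-style dump trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
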