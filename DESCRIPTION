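Package: dpdpull
Title: Dissipative Particle Dynamics of Polymer Chains Pulled Along or Off
    Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained dissipative particle dynamics (DPD) simulation and
    analysis of a linear bead-spring polymer interacting with a supported
    phospholipid bilayer under constant per-bead pulling forces. Provides a
    system builder (bilayer membrane, bulk solvent, surface-adsorbed polymer),
    a deterministic DPD engine (soft pair forces with pairwise thermostat,
    harmonic bonds, angle bending, anchored substrate beads, modified
    velocity-Verlet integration with periodic boundaries and cell-list
    neighbour search), and the standard conformational and membrane
    observables: radius of gyration, gyration-tensor shape factor,
    orientational order parameter profiles, slab head-bead counts, rod-coil
    transition periods and their exponential force dependence, plus
    reduced-to-physical unit mapping. A configuration-driven pipeline runs
    build/equilibrate/pull/analyze experiments with replicas, manifests and
    force sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
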