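Package: myowalk
Title: Hierarchic Coarse-Grained Simulation of Myosin-V Walking on Actin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hierarchic coarse-grained, Brownian-like simulator of the
    processive walking of a two-headed myosin-V motor along a closed circular
    actin track, together with the single-molecule trajectory statistics used
    to characterise such motors. Molecules are represented at three levels
    (secondary-structure sticks, domains, molecules) inside a tree of bounding
    volumes; motion is inertia-free fixed-step random displacement constrained
    by pairwise distance restraints, steric exclusion and an elastic dimer
    hinge. The actin-myosin interaction is a two-stage (loose/tight) binding
    state machine with an incremental 70 degree powerstroke and a recovery
    stroke. Analysis tools compute staircase position, step sizes, dwell-time
    exponential fits, duty ratios, velocities and binding-state coexistence
    tables from recorded trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
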