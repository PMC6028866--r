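Package: poremd
Title: Permeation, Gating and Electrostatics Analysis of Ion-Channel MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    tetrameric potassium channels. Provides binding-site occupancy and
    configuration-string bookkeeping for the selectivity filter,
    permeation-event counting and inferred single-channel current,
    density-based clustering of backbone carbonyl orientations for
    filter-gating analysis, grid-based Poisson electrostatics yielding
    electrical-distance profiles and gating charges, time-averaged
    lipid occupancy maps and per-residue lipid contacts, and
    docking-affinity post-processing (free energy to inhibition
    constant conversion and predicted-versus-experimental correlation).
    Ships seeded synthetic-system generators (filter scaffolds,
    scripted ion-hopping trajectories, parallel-plate voltage systems,
    toy bilayers, planted cluster sets) so the whole pipeline can be
    exercised end-to-end without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
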