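Package: tetrafold
Title: State Classification, Folding Thermodynamics and NMR Validation for
    RNA Tetraloop Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for conformational ensembles of the UUCG RNA
    tetraloop hairpin. Provides frame-level geometric primitives (distances,
    torsions, Kabsch superposition RMSD, sugar pseudorotation), a rule-based
    classifier assigning each trajectory frame to one of eleven published
    conformational states, the base-centric eRMSD metric with a two-state
    folded/unfolded indicator, folding free-energy estimation from folded
    populations with 16-block bootstrap errors, back-calculation of NMR
    observables (Karplus 3J couplings, r^-6 averaged NOEs and ambiguous
    NOEs) scored by a weighted total chi-square, and seeded synthetic-data
    generators so the whole pipeline can be exercised and validated without
    molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
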