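Package: flexiscreen
Title: Flexibility-Guided Stability Screening of Protein Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies highly flexible regions of a protein from conformational
    ensembles (multi-model PDB trajectories) via per-residue root mean square
    fluctuation (RMSF), triages designed point mutants by Rosetta ddG and by the
    percent change in region flexibility (delta-RMSF) between mutant and
    wild-type ensembles, and explains stabilisation through hydrogen-bond
    occupancy classes and three-state secondary-structure content. Includes a
    synthetic-ensemble generator with planted fluctuation amplitudes,
    hydrogen-bond occupancies and ideal backbone geometries so the full
    screening funnel is testable without molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
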