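Package: ancarea
Title: Ancestral Area Reconstruction for Historical Biogeography
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the ancestral geographic range of monophyletic clades
    from a rooted phylogeny and a taxon-area table, using three classical
    historical-biogeography methods: Fitch parsimony with full
    most-parsimonious-reconstruction (MPR) state sets, weighted ancestral
    area analysis (WAAA) with a per-area probability index, and exact
    dispersal-vicariance analysis (DIVA) by dynamic programming over area
    subsets with complete enumeration of optimal reconstructions.  Also
    provides a grid-based areas-of-endemism search with an explicit
    endemicity score and consensus step, and a simulator of
    vicariance/dispersal/extinction range histories with known ancestral
    ranges for validating every stage of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
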