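Package: revscreen
Title: Reverse Screening of Enzyme Sequence Space from Docking and
    Simulation Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in silico "reverse screening" toolkit for enzyme
    engineering, built around the PET-hydrolase (PETase) workflow:
    physicochemical conservation scoring of multiple sequence alignments
    and candidate-site nomination, exhaustive alanine-scanning and
    site-saturation variant enumeration, docking-pose leader clustering
    with geometric acceptance filters and mean-minus-SD selection of
    improved variants, sequence-space maps over mutation count, site and
    side-chain class, trajectory RMSD/RMSF/distance/hydrogen-bond
    analysis, and MM/PBSA bookkeeping (snapshot selection, Shrake-Rupley
    SASA apolar term, binding-energy totals and per-residue deltas).
    Docking, molecular dynamics and Poisson-Boltzmann engines are treated
    as replaceable inputs; a synthetic-data module generates every input
    with planted ground truth so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
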