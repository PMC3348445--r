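Package: ligover
Title: Flexible-Molecule Overlay and Pharmacophore Elucidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates, scores, filters, refines, multiplies and compares
    multiple alignments (overlays) of a set of small-molecule ligands supplied
    as multi-conformer SD files, producing ranked pharmacophore hypotheses.
    Overlays are generated with triplet-anchored Cartesian alignment
    fingerprints, scored with union-volume, hydrogen-bond, hydrophobic,
    strain-energy and custom-feature objectives, filtered by Fonseca-Fleming
    Pareto ranking with score constraints, Borda tallies and a diversity
    criterion, and compared with pharmacophore, geometric and consensus
    dissimilarity coefficients plus SMACOF multidimensional scaling.
    Simulated-annealing refinement and a multi-objective genetic algorithm
    for exploring alternative conformations under a fixed feature mapping
    are included, together with a synthetic toy-ligand generator with known
    true overlays for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
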