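Package: pocketconserve
Title: Structural Conservation of Ligand-Binding Pockets Across Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects putative ligand-binding pockets on protein structures
    with a grid-based protein-solvent-protein scan, superimposes the
    representative structures of a protein family onto a common reference,
    clusters pocket centers across the superimposed structures with a
    family-specific distance threshold, and scores each pocket cluster by
    its structural conservation (the fraction of representatives carrying
    the pocket). Clusters are further characterized by sequence
    conservation from a multiple sequence alignment, backbone flexibility
    from normalized B factors or NMR-ensemble fluctuations, and a screened
    Coulomb estimate of the electrostatic potential at the pocket center.
    Pairs of structurally conserved, spatially separated clusters are
    reported as candidate functional/allosteric site pairs. Includes a
    synthetic-fixture generator so every stage can be exercised and
    benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
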