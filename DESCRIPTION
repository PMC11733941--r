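Package: dmdgp
Title: Discretizable Distance Geometry for Protein Backbones with
    Frequency-Based Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the discretizable molecular distance geometry problem
    (DMDGP) on protein backbones. Builds the backbone vertex order with
    repeated alpha-carbons, encodes conformations as binary strings via
    plane-orientation bits, and solves exact distance-restraint instances
    with a symmetry-based build-up solver whose per-edge search is either
    left-first depth-first search or a frequency-based best-first search
    trained on previously solved segments. Includes a synthetic conformation
    and instance generator with idealized peptide geometry, frequency-table
    training with accumulated-probability curves, extraction of
    proline/glycine-free backbone segments from PDB files, and a
    depth-first versus frequency-based benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
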