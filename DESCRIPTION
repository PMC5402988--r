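Package: fragcoalesce
Title: Assembly and Scoring of Docked Peptide Fragments into Full-Length
    Disordered-Protein Complex Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles rigid-body docked 9-residue fragment poses of an
    intrinsically disordered protein (IDP) into full-length docked models
    on a receptor. Implements geometric compatibility filtering of fragment
    pairs, extend-and-cluster path assembly, consensus Z-score scoring of
    fragments (DI score), paths (Path Score) and models (Model Score),
    grid-search weight training, overlap-averaged backbone merging, CAPRI
    style evaluation metrics (fnat, interface RMSD, ligand RMSD), and a
    seeded synthetic-complex generator that emulates docking pose pools
    and opaque score channels for controlled benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
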