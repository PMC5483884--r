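Package: orthoscreen
Title: Orthology-Based Screening of Radiation-Response and DNA-Repair Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A file-based pipeline for cross-species comparative functional
    genomics. Computes Gene Ontology descendant closures from OBO snapshots,
    projects per-species GO annotation sets onto a reference plant through
    orthologue maps, partitions the projected sets into Venn cells to extract
    radiation-quality-exclusive biomarker candidates, scores protein-protein
    interaction networks by clique participation, and classifies
    OrthoMCL-style orthogroups between two taxa to pair characterized
    orthologues and infer genes in new functional roles. Ships seeded
    synthetic-corpus generators with planted ground truth so every stage is
    testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
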