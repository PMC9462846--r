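Package: synpan
Title: Synteny-Constrained Orthology and Pan-Genome Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects syntenic blocks and regions between annotated genomes of
    arbitrary ploidy from precomputed protein-similarity hits and orthogroup
    membership, collapses tandem arrays to representative genes, constrains
    anchors to orthogroups, chains collinear hits into blocks, optionally
    rescans for whole-genome-duplication (secondary) synteny, and decodes the
    pairwise syntenic orthologs into a reference-anchored pan-genome annotation
    exposing gene presence-absence and copy-number variation. A seeded
    genome-evolution simulator (inversions, translocations, tandem
    duplications, gene loss, whole-genome duplication, noisy bitscores)
    provides ground-truth fixtures so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
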