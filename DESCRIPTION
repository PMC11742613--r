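Package: trpcensus
Title: Tryptophan Census and Membrane-Depth Profiling for Multi-Spanning
    Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a proteome-wide amino-acid composition census
    stratified by transmembrane-domain count, with greedy
    sequence-identity redundancy filtering, membrane-slab placement and
    signed per-residue Calpha depth profiling of helical membrane-protein
    structure models, alignment-column information content and
    conserved-position ranking, and the rank-based and ANOVA group
    statistics used to compare tryptophan abundance and distribution
    between protein families such as the ceramide synthases. Seeded
    generators produce annotated synthetic proteomes, helical-bundle
    coordinate files with known membrane frames, and multiple sequence
    alignments with planted conserved columns, so every pipeline stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
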