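Package: gyraseq
Title: Single-Nucleotide Mapping of DNA Gyrase Cleavage Sites from
    Strand-Aware End Coverage
Version: 0.1.0
Authors@R:
    person("gyraseq", "developers", email = "gyraseq@example.org",
           role = c("aut", "cre"))
Description: Calls DNA gyrase cleavage sites (GCSs) at single-nucleotide
    resolution from strand-aware 3'-end coverage of poison-trapped cleavage
    complexes (Topo-Seq-style sample quartets), using a two-step coverage
    normalization against mock controls and the Audic-Claverie count test to
    detect paired 3'-end walls flanking the hallmark 4-bp gap left by the
    enzyme's staggered double-strand cleavage. Builds the 130-bp degenerate
    gyrase binding motif (position probability matrix, GC-content track with
    nucleosome-like periodicity), converts it to a log-odds weight
    matrix and scans sequences on both strands. Provides the enrichment
    statistics used to relate cleavage sites to genomic intervals,
    transcription units and genome bins (exact binomial, Fisher and
    conditional Poisson tests), and a synthetic-data simulator that emulates
    the statistical structure of the assay (wall-pinned fragment ends, 4-bp
    gap, sonication fragment sizes, ori-ter copy-number gradient, mock
    backgrounds) with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    BiocGenerics,
    optparse
Config/testthat/edition: 3
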