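Package: splicepairs
Title: Base Pair Geometry of snRNA Interactions with Human Splice Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing how the base-pair geometry of small nuclear
    RNA (snRNA) recognition loops explains the imperfect conservation of human
    splice sites. Classifies substrate:snRNA base pairs as Watson-Crick,
    isosteric or non-isosteric, scans splice junctions against the U5 snRNA
    Loop1 (and the homologous group IIA intron Id3 loop) in alternative
    binding registers, and tests positional base-pair frequency differences
    between intron classes with symmetrized Kullback-Leibler divergence,
    bootstrap-difference resampling and Bonferroni-Dunn corrections adjusted
    for correlated tests. Includes an intron dataset builder, a re-analysis of
    exon-start +1G mutation percent-spliced-in data, and a synthetic
    splice-site generator with tunable positional dependencies for testing
    the full pipeline without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    optparse
Config/testthat/edition: 3
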