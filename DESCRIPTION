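Package: asorf
Title: Conservation Analysis of Antisense Open Reading Frames Embedded in
    Prokaryotic Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects open reading frames (ORFs) fully embedded in antisense to
    annotated prokaryotic genes and quantifies their evolutionary conservation
    across a clade. Provides EMBOSS-needle-compatible global protein alignment
    with percent identity and percent similarity, per-family median pairwise
    conservation statistics, a codon-usage-driven mutation-accumulation null
    model of the identity-similarity relationship in sense and antisense
    reading frames, lower-quartile conservation classification against
    annotated single-copy ortholog families, strand-specific ribosome-profiling
    coverage tracks in reads per million after rRNA/tRNA read removal, and a
    synthetic clade simulator with known selection regimes for end-to-end
    validation and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
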