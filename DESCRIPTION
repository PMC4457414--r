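Package: ilescape
Title: Introner-Like Element Families and Spliceosomal Intron Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studying recent spliceosomal intron gain
    driven by Introner-Like Elements (ILEs) in fungal genomes. Clusters
    intron sequences into ILE families by single-linkage identity, builds
    IUPAC consensus sequences, derives family-specific and degenerate PCR
    primers from conserved alignment stretches and predicts amplicons by
    in-silico PCR. Projects intron positions of orthologous genes onto a
    shared protein-alignment coordinate frame, classifies every position
    against a species phylogeny (conserved, single presence, clade-restricted
    presence, presence-absence polymorphism, single absence), detects intron
    sliding candidates (positions closer than 15 nt) and calls parallel
    intron gains where an ILE sits next to a regular spliceosomal intron of
    a distant clade. Includes a forward simulator of gene-structure evolution
    along a phylogeny (substitutions, ILE/RSI gain, intron loss) with a
    ground-truth event log for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
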