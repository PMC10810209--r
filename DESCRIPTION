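Package: maecall
Title: Enhancer Calling for 25-bp Fragment Reporter Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of massively parallel reporter screens built
    on short (25 bp) random genomic fragments, where an unsorted input library
    and a fluorescence-sorted output library are sequenced and compared.
    Provides construct-anchored insert extraction from raw reads, alignment
    filtering and per-locus fragment counting, library-size and PCR-cycle
    aware count normalization with a zoom factor, a one-sided Poisson
    enrichment test with a compensation value for loci absent from the input,
    Benjamini-Hochberg selection, a compensation-multiplier calibration sweep,
    genomic annotation of called loci (chromatin marks, accessibility,
    known/novel status, gene features, TSS distance, loop anchors), a
    fragment-length unique-mappability simulation, and a synthetic screen
    generator with planted enhancers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: FunctionalGenomics, GeneRegulation, Sequencing, Software
RoxygenNote: 7.3.3
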