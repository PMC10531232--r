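Package: mammolnc
Title: Discovery, Profiling and Heritability Enrichment of Mammary lncRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable implementation of a long non-coding RNA (lncRNA)
    discovery and annotation workflow for bovine mammary transcriptomes.
    Assembled transcripts are filtered through a five-criterion cascade
    (intergenic position, length above 200 bp, absence of coding potential on
    both strands, no recognizable protein domain, no sequence homology to
    known genes), profiled for length, exon count and expression, tested for
    differential expression between dry and lactating tissue with a
    variance-guided choice between pooled and Welch t-tests, scored for
    sequence conservation over per-base tracks, correlated with coding-gene
    expression, and assessed for per-SNP heritability enrichment with a
    two-component genomic REML model and a delta-method standard error.
    Synthetic-data generators with planted ground truth make every stage
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
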