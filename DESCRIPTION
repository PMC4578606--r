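Package: promarch
Title: Core Promoter Architecture Analysis from TSS-Seq Tag Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of core promoter architecture from mapped 5' end
    (TSS-seq) read intervals: strand-aware tag clustering, promoter shape
    classification by the individual peakedness score Sg = m/(n*w),
    dominant-TSS core promoter extraction with transposon exclusion,
    per-position nucleotide composition profiling, annotation of the six
    canonical core promoter motifs (BREu, TATA, BREd, INR, MTE, DPE) by
    position weight matrix scanning with exact score-distribution p-values
    restricted to functional genomic windows, and downstream statistics:
    shuffled-background binomial enrichment, two- and three-way motif
    co-occurrence with confidence-interval flags, and percentile-rule gene
    ontology over-representation. Includes a deterministic synthetic-data
    generator (scaffolds, gene models, shaped TSS read distributions,
    planted motifs, transposons, GO maps) so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
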