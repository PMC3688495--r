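Package: bgcdelim
Title: Delineation and Evolutionary Classification of Secondary
    Metabolite Gene Clusters from Time-Course RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes a secondary-metabolite biosynthetic gene
    cluster around a backbone synthetase gene. Provides rule-based
    cluster prediction from role-annotated gene models, per-timepoint
    negative-binomial exact tests on replicated time-course count data
    with Benjamini-Hochberg false-discovery control and RPKM
    summaries, transcriptional delineation of the cluster boundary
    with three-way concordance reporting, and a flank-synteny /
    ortholog-dispersal analysis (reciprocal-best-hit orthology,
    intervening-gap measurement, homolog co-location scanning) that
    classifies the cluster's evolutionary origin as lineage-specific
    recruitment, a conserved cluster, a rearrangement, or a candidate
    horizontal transfer. A synthetic-data generator plants clusters
    with known boundaries, ortholog pairs and synteny scenarios so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
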