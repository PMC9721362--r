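Package: emsomics
Title: Integrated Genomic, Transcriptomic and Methylomic Analysis of EMS Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting chemically mutagenized (EMS) plant lines by
    combining three omics layers. Provides a seeded synthetic-data generator
    (toy genome, gene models, EMS-spectrum variants, two-library RNA-seq
    counts, bisulfite cytosine reports with planted truth), variant-effect
    annotation against gene models (region classes, codon-level consequences,
    Ti/Tv and mutation summaries), no-replicate differential-expression
    testing with TMM scaling and an exact conditional binomial test,
    bisulfite methylation-level estimation with non-conversion correction,
    binomial site calling, sliding-window aggregation and DMR detection,
    Gardiner-Garden and Frommer style CpG-island prediction with
    methylation-expression pattern classification, and three-way gene-set
    integration with a candidate report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR,
    jsonlite,
    vcfR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
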