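Package: adjacoex
Title: Copy-Number-Driven Co-Expression of Physically Adjacent Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dissecting why physically adjacent genes
    on an amplified chromosome arm are co-expressed. Screens genes for
    copy-number-driven (cis) expression using Pearson correlation between
    copy-number and mRNA levels, profiles genome-wide co-expression against
    seed genes, quantifies the cytoband distribution of co-expressed genes
    with hypergeometric positional enrichment, and groups significant genes
    into clusters of physically adjacent neighbours. Classifies adjacent
    gene pairs by orientation, extracts intergenic intervals, and annotates
    candidate bidirectional promoters with CpG-island, TATA-box and
    position-weight-matrix motif features. Partitions regulator target sets
    (transcription factors, microRNAs) across evidence sources with Venn
    logic, tests shared-regulator enrichment, and calls competing
    endogenous RNA (ceRNA) candidate pairs from shared-microRNA content,
    pair co-expression and microRNA anti-correlation. Includes a
    synthetic-data generator with planted ground truth (focal
    amplifications, cis effects, co-expression blocks, divergent promoter
    pairs, shared-microRNA coupling) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
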