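Package: dcescan
Title: Detection and Comparison of Domains of Co-ordinated Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Calls Domains of Co-ordinated Expression (DCEs) from bulk
        RNA-seq counts binned along chromosomes. Bin-level Spearman
        correlation matrices are made robust by a Monte-Carlo permutation
        mask, transformed into a one-dimensional bin signal by sliding
        juxtaposed windows, segmented at smoothed local minima, and the
        resulting domain boundaries are validated by rank-sum tests and
        refined by inward chopping, followed by a constrained fusion step.
        Companion tools compare two segmentations (Jaccard index, BP
        segmentation distance, seven-way domain-dynamics classification),
        extract disruptor genes from split events, run randomized-placement
        enrichment tests against gene sets and interval tracks, score
        enhancer-promoter link disruption, and simulate annotated count
        data with planted co-expression blocks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Coverage, Clustering
RoxygenNote: 7.3.3
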