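Package: mechanoCeRNA
Title: Layered Differential Expression, lncRNA Discovery and ceRNA
    Network Inference for Mechanically Stressed Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end reimplementation of a whole-transcriptome
    regulatory-landscape analysis for two-group RNA-seq designs spanning
    four expression layers (mRNA, miRNA, lncRNA, circRNA): count
    filtering, TMM normalization, a negative-binomial exact test with
    Benjamini-Hochberg adjustment and layer-specific calling rules,
    novel lncRNA discovery by intersecting coding-potential scores with
    an annotation screen, cis/trans/antisense lncRNA target assignment
    gated by Pearson correlation, competing endogenous RNA (ceRNA)
    network construction from seed-match miRNA target prediction,
    negative miRNA co-expression and a hypergeometric shared-miRNA
    test, and hypergeometric/GSEA functional enrichment. Includes a
    negative-binomial synthetic-data generator with planted ground
    truth for validating every stage.
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
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, DifferentialExpression, Network, GeneRegulation
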