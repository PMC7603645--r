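Package: lncage
Title: Multi-Tissue Aging Transcriptome Analysis of lncRNAs and mRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for charting aging-regulated long non-coding
    RNAs (lncRNAs) and mRNAs across a multi-tissue, multi-age bulk RNA-seq
    design. From a gene-level count matrix the pipeline performs TMM
    normalization, FPKM conversion and detectability filtering, calls
    aging-correlated and aging-regulated (AR) genes per tissue, computes
    fractional-expression tissue- and age-specificity scores, scores pairwise
    tissue similarity of AR gene sets, builds stage-binned AR-lncRNA~AR-mRNA
    co-expression networks with walktrap module detection and network-growth
    metrics, and runs local hypergeometric gene-set enrichment. A seeded
    negative-binomial study generator with planted aging, tissue-specificity
    and co-expression-module structure supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    edgeR,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
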