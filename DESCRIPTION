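Package: silkshift
Title: Evolution of Tissue-Specific Gene Expression Across Spider Silk Glands
Version: 0.1.0
Authors@R:
    person("silkshift", "developers", email = "silkshift@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for comparative analysis of gene-expression
    evolution across spider silk-gland types. Provides TMM normalization and
    FPKM computation, negative-binomial exact testing to call over-expressed
    silk transcripts (OESTs), Spearman-correlation clustering of transcripts
    and tissues with bootstrap support, cross-species gene-family
    aggregation, maximum-likelihood ancestral expression states under
    Brownian motion on gene trees, duplication-versus-speciation shift
    testing with Fisher's exact test, and the Fritz-Purvis D-statistic for
    phylogenetic signal of binary expression traits. A synthetic-data module
    generates gene trees, expression profiles and count matrices with the
    statistical structure the analysis assumes, including ground-truth
    labels for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
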