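Package: meditile
Title: Differential DNA Methylation Analysis for MeDIP Promoter Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for two-colour MeDIP-chip promoter tiling
    arrays: per-probe log2(MeDIP/Input) enrichment ratios, the M' group
    difference statistic, sliding-window peak calling with a multi-criterion
    differentially-enriched-peak (DEP) filter, CpG-density promoter
    classification (HCP/ICP/LCP), hypergeometric gene-set over-representation
    with Benjamini-Hochberg control, and MeDIP-qPCR / comparative-Ct
    quantification with two-factor ANOVA. Includes a synthetic two-channel
    array generator with known spike-in ground truth for benchmarking the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    car,
    fgsea,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
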