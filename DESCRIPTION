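Package: pleiopipe
Title: Cross-Trait Pleiotropy Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting shared genetic architecture between two
    traits from GWAS summary statistics: allele harmonization, reference-panel
    linkage-disequilibrium (LD) pruning and LD scores, empirical conditional
    and conjunction false discovery rates (cFDR/ccFDR) with pleiotropy
    enrichment diagnostics, five-hypothesis Bayesian regional colocalization
    via Wakefield approximate Bayes factors, unstratified LD score regression
    for heritability and genetic correlation, and two-sample Mendelian
    randomization (IVW and Egger). Includes a fully seeded synthetic-data
    generator (block-LD reference panels, four-component pleiotropy mixtures,
    a causally downstream outcome trait) so the whole pipeline is testable
    without consortium downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
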