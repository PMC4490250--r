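Package: snphub
Title: Multilayer Hub Discovery Among GWAS Loci from LD Blocks,
    Trans-eQTLs and Chromatin Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Collapses GWAS SNPs into linkage-disequilibrium haplotype-block
    loci (0.8 r2 or 0.8 D' rule), tests per-population Spearman SNP-expression
    associations with a cross-population replication verdict, assembles a
    multilayer locus graph from chromatin-contact (spatial), trans-eQTL and
    curated functional evidence, and detects regulatory hubs: sets of two or
    more GWAS loci connected directly or through intermediary loci. Ships a
    synthetic-data generator with planted ground truth (haplotype blocks,
    additive eQTL effects, hub contact lists) so every stage of the pipeline
    can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    optparse
Config/testthat/edition: 3
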