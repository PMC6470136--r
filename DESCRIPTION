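Package: cellHerit
Title: Cell-Type-Resolved Partitioned Heritability from GWAS Summary
    Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for connecting common-variant GWAS signal to tissues,
    cell types and gene sets. Builds binary SNP annotations from
    tissue- and cell-type-specific expression, eQTL tables,
    co-expression module assignments and curated gene sets; computes
    per-category LD scores and fits the stratified LD-score regression
    with block-jackknife standard errors and one-tailed coefficient
    tests; runs expression-weighted cell-type enrichment (EWCE) with
    covariate-matched bootstrap null lists; and aggregates SNP
    statistics into gene-level association p-values that account for
    local linkage disequilibrium. A synthetic-data module generates LD
    panels, summary statistics with known stratified heritability,
    expression matrices with planted markers and eQTL tables, so the
    whole pipeline is testable without consortium data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, GenomeWideAssociation, SNP, GeneExpression,
    SingleCell, Software
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
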