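# cellHerit

Cell-type-resolved partitioned heritability from GWAS summary
statistics.

## What problem this solves, and for whom

A GWAS tells you *where* common-variant risk lies in the genome, not
*which tissues, cell types or biological processes* it acts through.
For statistical geneticists asking that second question — e.g. whether
a neurodegenerative disease's heritability concentrates in neurons, in
glia, or in pathways expressed across many cell types — cellHerit
provides the full analysis chain:

* **Annotation builders** turn expression matrices, eQTL tables,
  co-expression module assignments and curated gene sets into binary
  SNP × category annotations (specificity ranking with category-aware
  t-statistics, top-decile selection, ±100 kb windows, eQTL assignment
  by maximal absolute slope, hypergeometric module labeling, MAF and
  MHC filters).
* **Stratified LD-score regression** estimates per-category
  heritability coefficients from the model

  E[χ²ⱼ] = N Σ_C τ_C ℓ(j,C) + N·a + 1,

  where ℓ(j,C) = Σ_{k∈C} r²ⱼₖ is SNP j's LD score with respect to
  category C. Inference is by delete-one block jackknife with a
  one-tailed coefficient test of τ_C > 0, plus heritability
  partitioning and enrichment.
* **Expression-weighted cell-type enrichment (EWCE)** tests whether a
  gene list's mean cell-type specificity s(g,c) = x_gc / Σ_c' x_gc'
  exceeds that of bootstrap gene lists matched on transcript length
  and GC content, with (1+k)/(1+B) p-values and BH adjustment over all
  gene sets × cell types of a run.
* **Gene-level association** aggregates SNP χ² within strand-aware
  35 kb/10 kb gene windows into a mean-statistic p-value whose null,
  Σ λᵢχ²₁ with λ the LD-matrix eigenvalues, is inverted numerically.
* A **synthetic-data module** (blockwise-exchangeable LD panels,
  summary statistics with known stratified structure, expression with
  planted markers, eQTL tables with planted effects) makes every stage
  testable end to end without consortium data.

## Worked example

```r
library(cellHerit)

panel <- simulateLdPanel(nIndividuals = 300, nBlocks = 20,
                         blockSize = 50, rho = 0.5, seed = 1)
v <- variants(panel)
set.seed(2)
annot <- annotationMatrix(v, list(
  base_all = rep(1L, nrow(v)),
  enriched = as.integer(blockIndex(panel) <= 5)))
ldsc  <- computeLdScores(panel, annot)
truth <- simTruth(c(base_all = 2e-7, enriched = 2e-6),
                  nGwas = 50000, seed = 3)
ss  <- simulateSumstats(panel, annot, truth, ldscores = ldsc)
fit <- fitStratified(ss, ldsc, nBlocks = 100)
fit
#> LdscFit (ldsc_weights, 100 jackknife blocks, 1000 SNPs)
#>   category       tau        se     z coefficient_p
#> 1 base_all 1.295e-06 6.650e-07 1.948     2.570e-02
#> 2 enriched 1.992e-06 3.002e-07 6.638     1.594e-11
#> intercept: 0.274 ( se 0.43 )
partitionHeritability(fit, annot)
#>   category prop_snps   prop_h2 enrichment
#> 1 base_all      1.00 1.0000000   1.000000
#> 2 enriched      0.25 0.4582911   1.833165
```

The `enriched` category was planted with coefficient 2e-6 and is
recovered at 1.99e-6 with a one-tailed coefficient p of 1.6e-11 —
holding 25% of SNPs but 46% of the heritability (1.83-fold
enrichment). For a report spanning two traits and the 53-category
baseline, the significance cut-off is
`bonferroniThreshold(0.05, 2, 53)` = 4.72e-4.

The EWCE arm works the same way from a specificity matrix; see the
vignette (`vignettes/cell-type-heritability.Rmd`) for a full tour of
the model, the defaults and the design decisions.

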