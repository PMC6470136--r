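---
title: "Partitioning GWAS heritability across tissues, cell types and gene sets"
author: "cellHerit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning GWAS heritability across tissues, cell types and gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellHerit)
```

# The scientific problem

A genome-wide association study localises risk to loci, not to the
tissues, cell types or biological processes through which those loci
act. For a complex disease such as Parkinson's disease — classically a
"neuronal" disorder, but with accumulating evidence for glial
involvement — the question *which cell types carry the common-variant
heritability?* is answerable from summary statistics alone, given
annotations that mark the genome by cell-type-specific activity.

cellHerit implements the two complementary machineries this kind of
analysis rests on, plus the annotation constructions feeding them and a
synthetic-data module that makes every stage testable without
consortium-scale inputs:

1. **Stratified LD-score regression.** For SNP $j$ with association
   statistic $\chi^2_j$ from a GWAS of $N$ individuals, the stratified
   model is
   $$\mathrm{E}[\chi^2_j] \;=\; N\sum_{C} \tau_C\,\ell(j,C)\; +\; Na + 1,$$
   where $\ell(j,C)=\sum_{k \in C} r^2_{jk}$ is the LD score of $j$
   with respect to annotation category $C$ (squared genotype
   correlations summed over in-window members of $C$), $\tau_C$ is the
   per-SNP heritability coefficient of $C$, and $a$ absorbs
   confounding inflation. Regressing $\chi^2_j$ on the per-category LD
   scores estimates $\tau_C$; a one-tailed test of $\tau_C > 0$ asks
   whether the category contributes heritability *beyond* the other
   categories in the model (in real analyses, a standing baseline of
   genomic architecture).

2. **Expression-weighted cell-type enrichment (EWCE).** For gene $g$
   and cell type $c$, specificity is the proportion of the gene's
   total expression found in that cell type,
   $s(g,c)=x_{gc}/\sum_{c'}x_{gc'}$. The enrichment statistic of a
   target gene list is its mean specificity per cell type, compared
   against bootstrap lists of random genes matched to the target's
   transcript length and GC content.

Around these sit the annotation builders (specificity ranking with
category-aware $t$-statistics, top-decile selection, ±100 kb window
expansion to binary SNP annotations, eQTL tissue assignment by maximal
absolute slope, co-expression-module labeling by hypergeometric marker
enrichment, curated gene sets) and an LD-aware gene-level association
test (mean-$\chi^2$ with a weighted-chi-square null).

# A worked run on simulated data

```{r simulate}
panel <- simulateLdPanel(nIndividuals = 300, nBlocks = 20,
                         blockSize = 50, rho = 0.5, seed = 1)
panel
v <- variants(panel)
set.seed(2)
annot <- annotationMatrix(v, list(
  base_all  = rep(1L, nrow(v)),
  enriched  = as.integer(blockIndex(panel) <= 5)))
ldsc <- computeLdScores(panel, annot)
truth <- simTruth(c(base_all = 2e-7, enriched = 2e-6),
                  nGwas = 50000, seed = 3)
ss <- simulateSumstats(panel, annot, truth, ldscores = ldsc)
fit <- fitStratified(ss, ldsc, nBlocks = 100)
fit
partitionHeritability(fit, annot)
```

The enriched category's coefficient should exceed its baseline share,
with the one-tailed p-value testing the positive contribution. The
Bonferroni threshold for a report spanning several traits and
categories comes from `bonferroniThreshold()`; for two traits against
the 53-category baseline it is `r signif(bonferroniThreshold(0.05, 2, 53), 3)`.

```{r ewce}
fx <- simulateExpression(800, paste0("ct", 1:6), markersPerGroup = 20,
                         fold = 8, noiseSd = 0.3, seed = 4)
spec <- specificityMatrix(fx@expr, geneCovariates(fx))
res <- ewceTest(fx@plantedMarkers$ct2, spec, nBoot = 5000,
                matching = "length_gc_bins", seed = 5)
ewceTable(res)
```

# Model and procedure notes

## The synthetic-data generators define the test conditions

* **LD panel.** Blocks are exchangeable: one allele frequency per
  block, and each haplotype allele is copied from a shared ancestral
  haplotype with probability $\sqrt{\rho}$, else drawn fresh. This
  makes the expected pairwise *genotype* correlation within a block
  exactly $\rho$ (so $\mathrm{E}[r^2]\approx\rho^2$ plus finite-sample
  noise $\approx 1/(n-1)$), keeps closed-form expectations available,
  and is deliberately simpler than distance-decaying LD: the point is
  to exercise $\ell(j,C)$ computation and the regression, not to mimic
  recombination. Blocks sit 3 Mb apart on one chromosome so the
  default 1 Mb LD window never spans blocks. Monomorphic draws are
  dropped with a message, as the downstream MAF filter would remove
  them anyway.
* **Summary statistics.** Each $\chi^2_j$ is a squared Gaussian with
  non-centrality chosen so the stratified expectation holds exactly;
  this is simpler than simulating phenotypes and is all the regression
  consumes. Expectations above 100 are rejected as configuration
  errors (such inflation is outside any plausible GWAS). Because the
  draws are independent across SNPs, this generator is the correct
  fixture for the regression but *not* for LD-aware gene-level tests;
  `simulateNullSumstats()` draws $Z$ from the per-block multivariate
  normal implied by the panel's empirical correlation for that
  purpose.
* **Expression fixtures.** Background expression is log-normal; group
  markers are planted multiplicatively at `fold`; `noiseSd` is in
  log2 units, the scale expression variability is conventionally
  quantified on. Transcript lengths are log-normal with median 2.5 kb
  (log-sd 0.6) and GC fractions Beta(5, 5), recorded in the fixture so
  covariate matching is testable. What the fixtures do **not** emulate:
  count-level sampling noise, dropout, batch structure, or correlated
  co-expression — so passing tests demonstrate correctness of the
  procedures, not robustness to every artefact of real RNA-seq.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| MAF floor | 0.05 | allele freq. | common-variant convention (strict >) |
| annotation window | 100,000 | bp | flank added around transcribed regions |
| top fraction | 0.1 | proportion | top decile of specificity scores |
| LD-score window | 1e6 | bp | fixed physical stand-in for a 1 cM map window; no genetic map is used |
| jackknife blocks | 200 | count | contiguous equal-count blocks, the field default |
| gene windows | 35,000 / 10,000 | bp | upstream/downstream regulatory flank, strand-aware |
| MHC exclusion | chr6:25.5–33.5 Mb | GRCh37 | long-range LD region |
| bootstraps | 100,000 | count | EWCE null lists (tests use fewer; see below) |
| matching bins | 10 × 10 | deciles | joint (length, GC) grid, marginal fallback |

## Numerical choices

* **Regression weights.** The default two-pass weighting uses
  $1/\max(\ell_j,1)\cdot 1/(2\hat y_j^2)$ with $\hat y$ from a first
  OLS pass, countering overcounting of correlated SNPs and the
  heteroskedasticity of $\chi^2$. First-pass fitted values are floored
  at 1 — the model's lower bound on $\mathrm{E}[\chi^2]$ — so weights
  stay finite when the first pass undershoots. Plain OLS is exposed as
  a fallback and results tables record which was used.
* **Jackknife.** Delete-one over contiguous SNP blocks via per-block
  cross-products (totals minus block), so 200 refits cost one pass.
  Coefficient p-values are clamped into the open unit interval so an
  exact fit (SE = 0) cannot emit a degenerate 0.
* **Collinearity.** A rank-deficient design names the offending
  categories and refuses to fit; an exact duplicate category is never
  silently absorbed. Empty categories are refused at fit time.
* **Weighted-chi-square inversion.** Gene p-values invert
  $\Pr\{\sum_i\lambda_i\chi^2_1 > q\}$ by Imhof-type numerical
  integration (relative tolerance 1e-12); equal-eigenvalue designs
  (one SNP, independent SNPs) short-circuit to the exact scaled
  chi-square, and a Satterthwaite moment match is the logged fallback
  if integration fails.
* **Fold-enrichment zero denominators.** A pseudocount of 1e-9 in the
  "mean of other cell types" denominator lets exclusively expressed
  genes rank above any finite competitor rather than erroring.
* **Tie-breaks.** Top-fraction selection breaks score ties at the
  cutoff by lexicographic gene id; eQTL effect-size ties go to the
  lexicographically first group, with a warning. Both are
  deterministic by construction.
* **Bootstrap p-values.** The $(1+k)/(1+B)$ convention guarantees
  $p \ge 1/(B+1)$; the sd-from-mean effect size is reported floored at
  0 (negative values reflect depletion) with the raw value retained.

## Design choices where the design was open

* The specificity $t$-statistic is a Welch two-sample test of a
  tissue's samples against samples of tissues in *other* categories:
  robust to unequal group sizes, and the zero-variance case is flagged
  `NA` rather than $\pm\infty$.
* eQTLs are collapsed by SNP id (not SNP–gene pair) before tissue
  assignment: the downstream annotation is a SNP set, so gene identity
  is irrelevant after collapse.
* FDR within tissue is Benjamini–Hochberg, the field default.
* "Predominantly one cell type" for module labeling is operationalised
  as *the unique* Bonferroni-significant class — the strictest
  defensible reading; modules significant for two classes stay
  unlabeled.
* Coordinates are 1-based inclusive in all tables (GTF-like); BED
  export converts to 0-based half-open at the boundary. The ±100 kb
  annotation windows ignore strand (the expansion is symmetric);
  gene-association windows honour it.
* EWCE covariate matching is per-gene (each bootstrap slot draws from
  the target gene's joint decile bin), with the nearest non-empty
  marginal length bin as logged fallback. BH adjustment spans all gene
  sets and cell types of one run, not across runs.
* The merged susceptibility list is the symmetric difference of the
  gene-association and eQTL-integration hits.
* The orchestration layer is a set of R functions (`runLdscArm()`,
  `runEwceArm()`, `validateAndManifest()`, YAML configs) rather than a
  shell executable: the package's users drive it from R, and the
  manifest records digests, resolved defaults and seeds so runs are
  reproducible and never silently overwrite differing prior results.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the regression studies at
5,000 SNPs in 50 LD blocks (N = 50,000; 100 recovery replicates, 1,000
size replicates), EWCE at 1,000 genes × 8 cell types with 1,000–10,000
bootstraps, and gene-level calibration over 500 single-block genes.
These sizes give stable Monte-Carlo estimates of the properties being
checked while keeping a full run in the low minutes; the procedures
themselves scale to consortium inputs since LD-score computation is
windowed ($O(m\cdot w)$) and the jackknife is single-pass.

## Known limitations

* Blockwise-exchangeable LD has no distance decay and no cross-block
  correlation; absolute LD-score magnitudes are not calibrated to any
  human reference.
* No genetic-map (cM) windows, no continuous-valued annotations, no
  cross-trait genetic correlation.
* The gene-level test implements the analytic mean-statistic null
  only; no permutation refinement for extreme p, and no top-SNP or
  PC-regression variants.
* WGCNA network construction, module preservation scoring, TWAS and
  colocalisation are upstream of this package: their outputs (module
  assignments, kME, preservation Z, gene lists) are consumed as
  inputs, and only the filters and labeling applied to them are
  implemented here.
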