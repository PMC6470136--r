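#' @import methods
NULL

## ---------------------------------------------------------------------------
## LdPanel: simulated (or loaded) reference genotype panel with LD blocks
## ---------------------------------------------------------------------------

#' LdPanel: a reference genotype panel with LD-block structure
#'
#' Holds an individuals x variants dosage matrix (entries 0/1/2), the
#' variant table describing the columns, and a per-variant LD-block label.
#' Monomorphic variants are never retained, so every realized MAF is
#' positive.
#'
#' @slot genotypes numeric matrix, individuals x variants, dosages in
#'   \{0,1,2\}; columns named by snp_id.
#' @slot variants the [variantTable()] describing the columns.
#' @slot blockIndex integer vector, one LD-block label per variant.
#' @slot nIndividuals number of individuals (rows).
#' @export
setClass("LdPanel", representation(
  genotypes    = "matrix",
  variants     = "data.frame",
  blockIndex   = "integer",
  nIndividuals = "integer"
))

setValidity("LdPanel", function(object) {
  g <- object@genotypes
  msgs <- character()
  if (!all(g %in% c(0, 1, 2)))
    msgs <- c(msgs, "dosages must be 0, 1 or 2")
  if (ncol(g) != nrow(object@variants))
    msgs <- c(msgs, "genotype columns must match variant rows")
  if (length(object@blockIndex) != ncol(g))
    msgs <- c(msgs, "blockIndex must have one entry per variant")
  if (nrow(g) != object@nIndividuals)
    msgs <- c(msgs, "nIndividuals must equal nrow(genotypes)")
  freq <- colMeans(g) / 2
  if (any(freq <= 0 | freq >= 1))
    msgs <- c(msgs, "monomorphic variants must be dropped")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## SimTruth: generating parameters of the stratified chi-square model
## ---------------------------------------------------------------------------

#' SimTruth: generating parameters for simulated summary statistics
#'
#' Records the per-category heritability coefficients tau (per-SNP
#' variance units), the intercept inflation term `a` of the chi-square
#' expectation `E[chi2_j] = N * sum_C tau_C * l(j,C) + N * a + 1`, the
#' GWAS sample size N and the simulation seed.
#'
#' @slot tau named numeric vector of per-category coefficients (>= 0).
#' @slot interceptInflation the `a` term (>= 0).
#' @slot nGwas GWAS sample size N (> 0).
#' @slot seed integer seed.
#' @export
setClass("SimTruth", representation(
  tau                = "numeric",
  interceptInflation = "numeric",
  nGwas              = "numeric",
  seed               = "integer"
))

setValidity("SimTruth", function(object) {
  msgs <- character()
  if (any(object@tau < 0)) msgs <- c(msgs, "tau entries must be >= 0")
  if (is.null(names(object@tau)) || anyDuplicated(names(object@tau)))
    msgs <- c(msgs, "tau must be named by unique category")
  if (object@interceptInflation < 0)
    msgs <- c(msgs, "interceptInflation must be >= 0")
  if (object@nGwas <= 0) msgs <- c(msgs, "nGwas must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @param tau named numeric vector of per-category coefficients.
#' @param interceptInflation the `a` inflation term; default 0.
#' @param nGwas GWAS sample size.
#' @param seed integer seed for the chi-square draws.
#' @rdname SimTruth-class
#' @return `simTruth()` returns a `SimTruth` object.
#' @export
simTruth <- function(tau, nGwas, interceptInflation = 0, seed = 1L) {
  new("SimTruth", tau = tau, interceptInflation = interceptInflation,
      nGwas = as.numeric(nGwas), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## AnnotationMatrix: binary SNP x category membership
## ---------------------------------------------------------------------------

#' AnnotationMatrix: binary SNP x category membership
#'
#' A SNP is scored 1 if it is present within the annotation and 0
#' otherwise. Category labels are unique; categories with no member SNP
#' are tolerated at construction but flagged, and the stratified
#' regression refuses to fit them.
#'
#' @slot variants the [variantTable()] defining the rows.
#' @slot membership integer matrix SNP x category with entries in \{0,1\};
#'   rows named by snp_id, columns by category.
#' @export
setClass("AnnotationMatrix", representation(
  variants   = "data.frame",
  membership = "matrix"
))

setValidity("AnnotationMatrix", function(object) {
  m <- object@membership
  msgs <- character()
  if (!all(m %in% c(0L, 1L)))
    msgs <- c(msgs, "membership entries must be 0 or 1")
  if (nrow(m) != nrow(object@variants))
    msgs <- c(msgs, "membership rows must match variants")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msgs <- c(msgs, "category labels must be unique and non-missing")
  if (length(msgs)) msgs else TRUE
})

#' Assemble an AnnotationMatrix from binary columns
#'
#' @param variants a [variantTable()].
#' @param columns named list (or matrix) of binary per-SNP indicator
#'   vectors, each of length `nrow(variants)`.
#' @return An [AnnotationMatrix-class] object. Empty categories trigger a
#'   warning; they can be stored but not regressed on.
#' @export
annotationMatrix <- function(variants, columns) {
  if (is.list(columns)) columns <- do.call(cbind, columns)
  storage.mode(columns) <- "integer"
  rownames(columns) <- variants$snp_id
  obj <- new("AnnotationMatrix", variants = variants, membership = columns)
  empty <- colSums(columns) == 0L
  if (any(empty))
    warning("empty annotation categories: ",
            paste(colnames(columns)[empty], collapse = ", "), call. = FALSE)
  obj
}

## ---------------------------------------------------------------------------
## LdScoreTable: per-SNP per-category LD scores
## ---------------------------------------------------------------------------

#' LdScoreTable: per-SNP, per-category LD scores
#'
#' l(j,C) is the sum over SNPs k in category C, within a physical window
#' of SNP j on the same chromosome, of the squared genotype correlation
#' r2_jk (including k = j when j is in C). `totalLd` is l(j) over all
#' panel SNPs in the window and is used for regression weighting.
#'
#' @slot snp character vector of SNP ids (row order).
#' @slot scores numeric matrix SNP x category of l(j,C).
#' @slot totalLd numeric vector l(j) over all SNPs.
#' @slot window physical window in bp.
#' @slot adjusted logical; TRUE if the finite-sample r2 adjustment
#'   `r2 - (1 - r2)/(n - 2)` was applied.
#' @export
setClass("LdScoreTable", representation(
  snp      = "character",
  scores   = "matrix",
  totalLd  = "numeric",
  window   = "numeric",
  adjusted = "logical"
))

setValidity("LdScoreTable", function(object) {
  msgs <- character()
  if (nrow(object@scores) != length(object@snp))
    msgs <- c(msgs, "scores rows must match snp ids")
  if (length(object@totalLd) != length(object@snp))
    msgs <- c(msgs, "totalLd must have one entry per SNP")
  if (!object@adjusted && any(object@scores < 0))
    msgs <- c(msgs, "unadjusted LD scores must be >= 0")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## SumStats: GWAS summary statistics for one trait
## ---------------------------------------------------------------------------

#' SumStats: per-SNP chi-square statistics for one GWAS trait
#'
#' @slot snp SNP ids.
#' @slot chi2 per-SNP chi-square (Z^2), all >= 0.
#' @slot z signed Z score (sign is arbitrary for simulated data).
#' @slot n GWAS sample size; scalar or per-SNP.
#' @slot trait trait label.
#' @export
setClass("SumStats", representation(
  snp   = "character",
  chi2  = "numeric",
  z     = "numeric",
  n     = "numeric",
  trait = "character"
))

setValidity("SumStats", function(object) {
  msgs <- character()
  if (any(object@chi2 < 0)) msgs <- c(msgs, "chi2 must be >= 0")
  if (length(object@chi2) != length(object@snp))
    msgs <- c(msgs, "chi2 must have one entry per SNP")
  if (!(length(object@n) %in% c(1L, length(object@snp))) ||
      any(object@n <= 0))
    msgs <- c(msgs, "n must be positive, scalar or per-SNP")
  if (length(msgs)) msgs else TRUE
})

#' @param snp SNP ids.
#' @param z signed Z scores (chi2 is z^2), or NULL if `chi2` given.
#' @param chi2 per-SNP chi-square; derived from `z` when missing.
#' @param n sample size.
#' @param trait trait label.
#' @rdname SumStats-class
#' @return `sumStats()` returns a `SumStats` object.
#' @export
sumStats <- function(snp, z = NULL, chi2 = NULL, n, trait = "trait") {
  if (is.null(chi2)) chi2 <- z^2
  if (is.null(z)) z <- sqrt(chi2)
  new("SumStats", snp = as.character(snp), chi2 = chi2, z = z,
      n = as.numeric(n), trait = trait)
}

## ---------------------------------------------------------------------------
## LdscFit: fitted stratified regression
## ---------------------------------------------------------------------------

#' LdscFit: a fitted stratified LD-score regression
#'
#' Per-category coefficients tau with delete-one block-jackknife standard
#' errors, coefficient z = tau/se and one-tailed upper p-values (testing
#' whether the category positively contributes to trait heritability),
#' plus the free intercept (1 + N*a under the model).
#'
#' @slot categories category labels.
#' @slot tau per-category coefficient estimates.
#' @slot se jackknife standard errors.
#' @slot z coefficient z-scores.
#' @slot p one-tailed upper-tail normal p-values.
#' @slot intercept intercept estimate.
#' @slot interceptSe jackknife SE of the intercept.
#' @slot nBlocks number of jackknife blocks used.
#' @slot nSnps number of regression SNPs.
#' @slot weighting "ldsc_weights" or "ols".
#' @slot trait trait label carried from the summary statistics.
#' @export
setClass("LdscFit", representation(
  categories  = "character",
  tau         = "numeric",
  se          = "numeric",
  z           = "numeric",
  p           = "numeric",
  intercept   = "numeric",
  interceptSe = "numeric",
  nBlocks     = "integer",
  nSnps       = "integer",
  weighting   = "character",
  trait       = "character"
))

setValidity("LdscFit", function(object) {
  msgs <- character()
  k <- length(object@categories)
  if (length(object@tau) != k || length(object@se) != k ||
      length(object@z) != k || length(object@p) != k)
    msgs <- c(msgs, "per-category vectors must share length")
  if (any(object@p <= 0 | object@p >= 1, na.rm = TRUE))
    msgs <- c(msgs, "one-tailed p must lie in (0,1)")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## ExpressionFixture: simulated expression with planted markers
## ---------------------------------------------------------------------------

#' ExpressionFixture: simulated gene x group mean expression
#'
#' Nonnegative mean-expression matrix over tissues or cell types, with
#' per-gene transcript length (bp) and GC fraction covariates and a
#' record of which genes were planted as group-specific markers.
#'
#' @slot expr nonnegative gene x group matrix.
#' @slot geneMeta data.frame with `length_bp` and `gc`, one row per gene.
#' @slot plantedMarkers named list: group -> planted marker gene ids
#'   (disjoint across groups).
#' @export
setClass("ExpressionFixture", representation(
  expr           = "matrix",
  geneMeta       = "data.frame",
  plantedMarkers = "list"
))

setValidity("ExpressionFixture", function(object) {
  msgs <- character()
  if (any(object@expr < 0)) msgs <- c(msgs, "expression must be nonnegative")
  if (nrow(object@geneMeta) != nrow(object@expr) ||
      !identical(rownames(object@geneMeta), rownames(object@expr)))
    msgs <- c(msgs, "geneMeta must cover every gene in expr, in order")
  if (any(object@geneMeta$gc < 0 | object@geneMeta$gc > 1))
    msgs <- c(msgs, "GC fraction must lie in [0,1]")
  planted <- unlist(object@plantedMarkers, use.names = FALSE)
  if (anyDuplicated(planted))
    msgs <- c(msgs, "planted markers must be disjoint across groups")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## SpecificityMatrix: gene x cell-type proportions of total expression
## ---------------------------------------------------------------------------

#' SpecificityMatrix: per-gene proportions of total expression
#'
#' Each retained row sums to 1: s(g,c) is the proportion of gene g's
#' summed expression found in cell type c. Genes with zero total
#' expression are excluded before normalization and listed in `dropped`.
#'
#' @slot specificity gene x cell-type matrix of proportions in [0,1].
#' @slot covariates data.frame with per-gene `length_bp` and `gc` (may
#'   have zero columns when no covariates were supplied).
#' @slot dropped gene ids excluded for zero total expression.
#' @export
setClass("SpecificityMatrix", representation(
  specificity = "matrix",
  covariates  = "data.frame",
  dropped     = "character"
))

setValidity("SpecificityMatrix", function(object) {
  s <- object@specificity
  msgs <- character()
  if (any(s < 0 | s > 1)) msgs <- c(msgs, "specificity must lie in [0,1]")
  if (nrow(s) && any(abs(rowSums(s) - 1) > 1e-9))
    msgs <- c(msgs, "specificity rows must sum to 1 (+/- 1e-9)")
  if (ncol(object@covariates) &&
      !identical(rownames(object@covariates), rownames(s)))
    msgs <- c(msgs, "covariates must be row-aligned with specificity")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## EwceResult: bootstrap cell-type enrichment of a gene list
## ---------------------------------------------------------------------------

#' EwceResult: expression-weighted cell-type enrichment results
#'
#' One row per cell type: the observed mean specificity of the target
#' list, the bootstrap mean and SD, standard deviations from the mean
#' (reported floored at 0; the raw value is kept), the bootstrap p-value
#' under the (1+k)/(1+B) convention and its BH adjustment over the cell
#' types of this run.
#'
#' @slot results data.frame with columns `cell_type`, `observed`,
#'   `boot_mean`, `boot_sd`, `sd_from_mean_raw`, `sd_from_mean`, `p`, `q`.
#' @slot nBoot number of bootstrap lists.
#' @slot matching "none" or "length_gc_bins".
#' @slot targetUsed target gene ids present in the specificity matrix.
#' @slot targetMissing target gene ids absent from it.
#' @slot binFallbacks character log of marginal-bin fallbacks.
#' @export
setClass("EwceResult", representation(
  results       = "data.frame",
  nBoot         = "integer",
  matching      = "character",
  targetUsed    = "character",
  targetMissing = "character",
  binFallbacks  = "character"
))

setValidity("EwceResult", function(object) {
  r <- object@results
  msgs <- character()
  if (any(r$sd_from_mean < 0)) msgs <- c(msgs, "sd_from_mean must be >= 0")
  if (any(r$p <= 0 | r$p > 1)) msgs <- c(msgs, "p must lie in (0,1]")
  if (length(msgs)) msgs else TRUE
})
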