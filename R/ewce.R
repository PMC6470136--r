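## Expression-weighted cell-type enrichment: specificity matrix plus a
## covariate-matched bootstrap test of whether a target gene list is more
## specifically expressed in a cell type than chance.

#' Build a specificity matrix from mean expression
#'
#' Cell-type specificity of a gene is the proportion of its total
#' expression found in one cell type: `s(g,c) = expr(g,c) / sum_c'
#' expr(g,c')`. Genes with zero total expression are dropped before
#' normalization and listed in the result.
#'
#' @param meanExpr nonnegative gene x cell-type matrix (>= 2 cell types).
#' @param covariates optional data.frame with per-gene `length_bp` and
#'   `gc`, rownames covering the genes of `meanExpr` (used for
#'   covariate-matched bootstraps).
#' @return A [SpecificityMatrix-class].
#' @export
#' @examples
#' m <- matrix(c(2, 1, 1, 5, 0, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("a", "b", "c")))
#' specificity(specificityMatrix(m))
specificityMatrix <- function(meanExpr, covariates = NULL) {
  if (ncol(meanExpr) < 2)
    stop("need >= 2 cell types to define specificity", call. = FALSE)
  if (any(meanExpr < 0))
    stop("expression must be nonnegative", call. = FALSE)
  tot <- rowSums(meanExpr)
  dropped <- rownames(meanExpr)[tot == 0]
  if (length(dropped))
    .msg("dropping %d zero-expression gene(s)", length(dropped))
  keep <- tot > 0
  s <- meanExpr[keep, , drop = FALSE] / tot[keep]
  cov <- if (is.null(covariates)) {
    data.frame(row.names = rownames(s))
  } else {
    if (!all(rownames(s) %in% rownames(covariates)))
      stop("covariates must cover every retained gene", call. = FALSE)
    covariates[rownames(s), , drop = FALSE]
  }
  new("SpecificityMatrix", specificity = s, covariates = cov,
      dropped = dropped)
}

## decile (or fewer, under ties) bin index for one covariate
.decileBins <- function(x, nBins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Expression-weighted cell-type enrichment bootstrap test
#'
#' The statistic for each cell type is the mean specificity of the target
#' genes. The null is `nBoot` random gene lists of the same size; with
#' `matching = "length_gc_bins"` each bootstrap gene is drawn from the
#' same joint decile bin of (transcript length, GC fraction) as the
#' corresponding target gene, falling back to the nearest non-empty
#' marginal length bin when a joint bin is empty (logged in the result).
#' The p-value uses the permutation convention `(1 + k)/(1 + nBoot)`
#' (never exactly 0), and the enrichment effect size is standard
#' deviations from the bootstrap mean, reported floored at 0 (negative
#' values reflect depletion); the raw value is retained.
#'
#' @param target character vector of target gene ids. Genes absent from
#'   the specificity matrix are logged; an overlap rate below 10%
#'   suggests a gene-id namespace mismatch and is an error.
#' @param spec a [SpecificityMatrix-class].
#' @param nBoot number of bootstrap lists (>= 100); the study convention
#'   is 100,000.
#' @param matching `"none"` or `"length_gc_bins"`.
#' @param nBins bins per covariate for matching; default 10 (deciles).
#' @param seed integer seed.
#' @return An [EwceResult-class]; q-values are BH over this run's cell
#'   types. For a joint family over several gene sets use
#'   [runEwceArm()].
#' @export
ewceTest <- function(target, spec, nBoot = 100000,
                     matching = c("none", "length_gc_bins"), nBins = 10,
                     seed = 1L) {
  matching <- match.arg(matching)
  stopifnot(is(spec, "SpecificityMatrix"))
  nBoot <- .checkCount(nBoot, "nBoot", min = 100L)
  s <- specificity(spec)
  target <- unique(target)
  used <- intersect(target, rownames(s))
  missing <- setdiff(target, rownames(s))
  if (!length(used))
    stop("no target gene is present in the specificity matrix",
         call. = FALSE)
  if (length(used) / length(target) < 0.1)
    stop("under 10% of target genes match the specificity matrix: ",
         "likely a gene-id namespace mismatch", call. = FALSE)

  nGenes <- nrow(s)
  L <- length(used)
  observed <- colMeans(s[used, , drop = FALSE])

  set.seed(as.integer(seed))
  fallbacks <- character()
  if (matching == "length_gc_bins") {
    cov <- geneCovariates(spec)
    if (!all(c("length_bp", "gc") %in% colnames(cov)))
      stop("matching needs 'length_bp' and 'gc' covariates", call. = FALSE)
    lenBin <- .decileBins(cov$length_bp, nBins)
    gcBin <- .decileBins(cov$gc, nBins)
    joint <- (lenBin - 1L) * (max(gcBin)) + gcBin
    byJoint <- split(seq_len(nGenes), joint)
    byLen <- split(seq_len(nGenes), lenBin)
    tIdx <- match(used, rownames(s))
    idx <- matrix(0L, L, nBoot)
    for (i in seq_len(L)) {
      pool <- byJoint[[as.character(joint[tIdx[i]])]]
      if (is.null(pool) || !length(pool)) {
        # nearest non-empty marginal length bin
        tb <- lenBin[tIdx[i]]
        cand <- as.integer(names(byLen))
        near <- cand[which.min(abs(cand - tb))]
        pool <- byLen[[as.character(near)]]
        fallbacks <- c(fallbacks, sprintf(
          "gene %s: joint bin empty, marginal length bin %d used",
          used[i], near))
      }
      idx[i, ] <- pool[sample.int(length(pool), nBoot, replace = TRUE)]
    }
  } else {
    idx <- matrix(sample.int(nGenes, L * nBoot, replace = TRUE), L, nBoot)
  }

  # bootstrap statistics: mean specificity per list, per cell type
  flat <- s[as.vector(idx), , drop = FALSE]
  bootId <- rep(seq_len(nBoot), each = L)
  bootStat <- rowsum(flat, bootId, reorder = FALSE) / L

  k <- colSums(sweep(bootStat, 2, observed, ">=") * 1)
  p <- (1 + k) / (1 + nBoot)
  bm <- colMeans(bootStat)
  bs <- apply(bootStat, 2, stats::sd)
  sdRaw <- (observed - bm) / bs
  res <- data.frame(
    cell_type = colnames(s), observed = unname(observed),
    boot_mean = unname(bm), boot_sd = unname(bs),
    sd_from_mean_raw = unname(sdRaw),
    sd_from_mean = pmax(unname(sdRaw), 0),
    p = unname(p), q = stats::p.adjust(unname(p), method = "BH"),
    row.names = NULL)
  if (length(fallbacks)) .msg("%d bin fallback(s)", length(fallbacks))
  new("EwceResult", results = res, nBoot = nBoot, matching = matching,
      targetUsed = used, targetMissing = missing,
      binFallbacks = fallbacks)
}

#' Merge gene-level susceptibility lists, dropping the overlap
#'
#' Combines a set of genome-wide-significant gene-association hits with
#' an eQTL-based (TWAS/colocalisation) gene set by taking their symmetric
#' difference: the union minus the genes present in both.
#'
#' @param magmaHits character vector of genome-wide-significant genes.
#' @param twasColoc character vector from eQTL-integration analyses.
#' @return Sorted character vector; identical inputs produce an empty
#'   list with a warning.
#' @export
#' @examples
#' susceptibilityGeneList(c("A", "B", "C"), c("C", "D"))
susceptibilityGeneList <- function(magmaHits, twasColoc) {
  magmaHits <- unique(magmaHits)
  twasColoc <- unique(twasColoc)
  out <- sort(union(setdiff(magmaHits, twasColoc),
                    setdiff(twasColoc, magmaHits)))
  if (!length(out) && (length(magmaHits) || length(twasColoc)))
    warning("the two gene sets are identical; the merged list is empty",
            call. = FALSE)
  out
}
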