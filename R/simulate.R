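## Synthetic-data generators: LD panels, summary statistics with known
## stratified heritability, expression matrices with planted markers, and
## eQTL tables. Everything is deterministic given its seed.

#' Simulate a blockwise-exchangeable LD reference panel
#'
#' Generates an individuals x variants dosage panel organised in LD
#' blocks. Within a block all variants share one allele frequency (drawn
#' uniformly from `mafRange`) and each haplotype allele is copied from a
#' shared ancestral haplotype with probability `sqrt(rho)`, otherwise
#' drawn fresh; this makes the expected pairwise genotype correlation
#' within a block exactly `rho`, while variants in different blocks are
#' independent. Blocks are placed 3 Mb apart on one chromosome with 1 kb
#' spacing inside a block, so positions are strictly increasing.
#' Monomorphic variants are dropped (with a message) and the recorded MAF
#' is the realized minor-allele frequency.
#'
#' @param nIndividuals number of individuals (>= 25).
#' @param nBlocks number of LD blocks.
#' @param blockSize variants per block (>= 1).
#' @param rho within-block genotype correlation in [0, 1).
#' @param mafRange allele-frequency interval for the block MAF draws;
#'   must be non-degenerate and inside (0, 0.5].
#' @param seed integer seed.
#' @param chromosome chromosome label for all variants; default "1".
#' @return An [LdPanel-class].
#' @export
#' @examples
#' panel <- simulateLdPanel(200, nBlocks = 4, blockSize = 10, rho = 0.6,
#'                          seed = 1)
#' panel
simulateLdPanel <- function(nIndividuals, nBlocks, blockSize, rho,
                            mafRange = c(0.05, 0.5), seed = 1L,
                            chromosome = "1") {
  nIndividuals <- .checkCount(nIndividuals, "nIndividuals", min = 25L)
  nBlocks <- .checkCount(nBlocks, "nBlocks")
  blockSize <- .checkCount(blockSize, "blockSize")
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)", call. = FALSE)
  if (length(mafRange) != 2L || mafRange[1] >= mafRange[2] ||
      mafRange[1] <= 0 || mafRange[2] > 0.5)
    stop("degenerate 'mafRange': need 0 < min < max <= 0.5", call. = FALSE)

  set.seed(as.integer(seed))
  m <- nBlocks * blockSize
  copyP <- sqrt(rho)
  geno <- matrix(0L, nIndividuals, m)
  blockMaf <- stats::runif(nBlocks, mafRange[1], mafRange[2])
  for (b in seq_len(nBlocks)) {
    cols <- ((b - 1L) * blockSize + 1L):(b * blockSize)
    p <- blockMaf[b]
    for (h in 1:2) {  # two haplotypes per individual
      anc <- stats::rbinom(nIndividuals, 1L, p)
      copy <- matrix(stats::rbinom(nIndividuals * blockSize, 1L, copyP),
                     nIndividuals, blockSize)
      fresh <- matrix(stats::rbinom(nIndividuals * blockSize, 1L, p),
                      nIndividuals, blockSize)
      geno[, cols] <- geno[, cols] + copy * anc + (1L - copy) * fresh
    }
  }

  block <- rep(seq_len(nBlocks), each = blockSize)
  pos <- (block - 1L) * 3000000L + (seq_len(m) - (block - 1L) * blockSize) *
    1000L
  freq <- colMeans(geno) / 2
  poly <- freq > 0 & freq < 1
  if (any(!poly))
    .msg("dropping %d monomorphic simulated variant(s)", sum(!poly))
  geno <- geno[, poly, drop = FALSE]
  maf <- pmin(freq[poly], 1 - freq[poly])
  snp <- sprintf("rs%06d", which(poly))
  colnames(geno) <- snp
  vt <- variantTable(data.frame(
    snp_id = snp, chromosome = chromosome, position = pos[poly],
    a1 = "A", a2 = "G", maf = maf, stringsAsFactors = FALSE))
  new("LdPanel", genotypes = geno, variants = vt,
      blockIndex = block[poly], nIndividuals = nIndividuals)
}

#' Simulate GWAS summary statistics under the stratified model
#'
#' Draws per-SNP chi-square statistics with expectation
#' `E[chi2_j] = N * sum_C tau_C * l(j,C) + N * a + 1`, where l(j,C) are
#' LD scores computed from the panel. Each chi-square is a squared
#' Gaussian with the non-centrality the expectation implies (mean
#' `sqrt(E[chi2_j] - 1)`, unit variance), so the model expectation holds
#' exactly. Expectations above `maxExpectedChi2` are rejected as
#' implausible inflation.
#'
#' @param panel an [LdPanel-class].
#' @param annot an [AnnotationMatrix-class] defined on the panel's
#'   variants; categories must match `names(truth@tau)`.
#' @param truth a [simTruth()] object.
#' @param window LD-score window in bp; default 1e6.
#' @param maxExpectedChi2 upper sanity bound on any per-SNP expectation;
#'   default 100.
#' @param ldscores optional precomputed [LdScoreTable-class] for the
#'   panel/annotation pair (replicate loops reuse one table instead of
#'   recomputing it per draw).
#' @return A [SumStats-class] with trait label `"simulated"`.
#' @export
simulateSumstats <- function(panel, annot, truth, window = 1e6,
                             maxExpectedChi2 = 100, ldscores = NULL) {
  stopifnot(is(panel, "LdPanel"), is(annot, "AnnotationMatrix"),
            is(truth, "SimTruth"))
  if (!identical(variants(panel)$snp_id, variants(annot)$snp_id))
    stop("annotation and panel variant universes differ", call. = FALSE)
  tau <- truth@tau
  if (!identical(sort(names(tau)), sort(categories(annot))))
    stop("tau categories must match annotation categories", call. = FALSE)
  lt <- if (is.null(ldscores)) {
    computeLdScores(panel, annot, window = window)
  } else {
    stopifnot(is(ldscores, "LdScoreTable"),
              identical(ldscores@snp, variants(panel)$snp_id))
    ldscores
  }
  mu <- 1 + truth@nGwas *
    (as.vector(ldScores(lt)[, names(tau), drop = FALSE] %*% tau) +
       truth@interceptInflation)
  if (any(mu > maxExpectedChi2))
    stop(sprintf(
      "implausible inflation: max E[chi2] = %.1f exceeds bound %.1f",
      max(mu), maxExpectedChi2), call. = FALSE)
  set.seed(truth@seed)
  z <- stats::rnorm(length(mu), mean = sqrt(mu - 1)) *
    sample(c(-1, 1), length(mu), replace = TRUE)
  sumStats(variants(panel)$snp_id, z = z, n = truth@nGwas,
           trait = "simulated")
}

#' Simulate null summary statistics with LD-correlated Z scores
#'
#' Under the global null the Z statistics of nearby SNPs are correlated
#' according to local LD. This generator draws, per LD block, Z from a
#' multivariate normal with the panel's empirical genotype correlation
#' matrix, giving the correct null for LD-aware gene-level tests.
#'
#' @param panel an [LdPanel-class].
#' @param nGwas GWAS sample size to record.
#' @param seed integer seed.
#' @return A [SumStats-class] with trait label `"null"`.
#' @export
simulateNullSumstats <- function(panel, nGwas, seed = 1L) {
  stopifnot(is(panel, "LdPanel"))
  set.seed(as.integer(seed))
  g <- genotypes(panel)
  blk <- blockIndex(panel)
  z <- numeric(ncol(g))
  for (b in unique(blk)) {
    cols <- which(blk == b)
    R <- stats::cor(g[, cols, drop = FALSE])
    ev <- eigen(R, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(cols))
    z[cols] <- as.vector(L %*% stats::rnorm(length(cols)))
  }
  sumStats(variants(panel)$snp_id, z = z, n = nGwas, trait = "null")
}

#' Simulate mean expression with planted cell-type markers
#'
#' Background expression per gene is log-normal (median 10 expression
#' units) and identical across groups up to multiplicative log-normal
#' noise with log-sd `noiseSd`; each group's planted markers get their
#' expression multiplied by `fold` in that group only. `noiseSd` is in
#' log2 units, the scale expression variability is conventionally
#' quantified on. Transcript lengths
#' are log-normal with median 2.5 kb (log-sd 0.6) and GC fractions are
#' Beta(5, 5); both are recorded so covariate-matched bootstraps are
#' testable.
#'
#' @param nGenes number of genes.
#' @param groups character vector of group (tissue/cell-type) labels.
#' @param markersPerGroup planted markers per group;
#'   `markersPerGroup * length(groups)` must not exceed `nGenes`.
#' @param fold marker fold-change, must be > 1.
#' @param noiseSd log2-scale noise sd (0 gives a noiseless fixture).
#' @param seed integer seed.
#' @return An [ExpressionFixture-class].
#' @export
simulateExpression <- function(nGenes, groups, markersPerGroup, fold,
                               noiseSd = 0.3, seed = 1L) {
  nGenes <- .checkCount(nGenes, "nGenes")
  markersPerGroup <- .checkCount(markersPerGroup, "markersPerGroup",
                                 min = 0L)
  if (fold <= 1)
    stop("'fold' must be > 1: markers would be undetectable", call. = FALSE)
  if (noiseSd < 0) stop("'noiseSd' must be >= 0", call. = FALSE)
  k <- length(groups)
  if (markersPerGroup * k > nGenes)
    stop("markersPerGroup * |groups| exceeds nGenes", call. = FALSE)

  set.seed(as.integer(seed))
  gene <- sprintf("gene%05d", seq_len(nGenes))
  base <- stats::rlnorm(nGenes, meanlog = log(10), sdlog = 1)
  expr <- matrix(rep(base, k), nGenes, k,
                 dimnames = list(gene, groups))
  planted <- vector("list", k)
  names(planted) <- groups
  if (markersPerGroup > 0) {
    idx <- sample(nGenes, markersPerGroup * k)
    for (i in seq_len(k)) {
      rows <- idx[((i - 1L) * markersPerGroup + 1L):(i * markersPerGroup)]
      expr[rows, i] <- expr[rows, i] * fold
      planted[[i]] <- gene[rows]
    }
  } else {
    planted[] <- list(character())
  }
  if (noiseSd > 0)  # noiseSd is in log2 units
    expr <- expr * matrix(stats::rlnorm(nGenes * k, 0, noiseSd * log(2)),
                          nGenes, k)
  meta <- data.frame(
    length_bp = round(stats::rlnorm(nGenes, log(2500), 0.6)),
    gc = stats::rbeta(nGenes, 5, 5),
    row.names = gene)
  new("ExpressionFixture", expr = expr, geneMeta = meta,
      plantedMarkers = planted)
}

#' Simulate per-tissue eQTL association tables
#'
#' Every planted association appears in its tissue's table with a small
#' p-value drawn from the alternative (uniform below `altPMax`), plus
#' `round(nullPFraction * n_snps)` filler associations per tissue with
#' p ~ Uniform(0, 1) and small random slopes. Slopes are stored signed.
#'
#' @param panel an [LdPanel-class] supplying the SNP universe.
#' @param genes a [geneTable()] supplying the gene universe.
#' @param tissues non-empty character vector of tissue labels.
#' @param effectPlan data.frame with columns `snp_id`, `gene_id`,
#'   `tissue`, `slope` (finite, signed); may have zero rows.
#' @param nullPFraction number of uniform-p filler rows per tissue, as a
#'   fraction of the panel SNP count; default 0.5.
#' @param altPMax upper bound for planted p-values; default 1e-8.
#' @param seed integer seed.
#' @return Named list of per-tissue data.frames with columns `snp_id`,
#'   `gene_id`, `tissue`, `slope`, `p`.
#' @export
simulateEqtlTables <- function(panel, genes, tissues, effectPlan,
                               nullPFraction = 0.5, altPMax = 1e-8,
                               seed = 1L) {
  stopifnot(is(panel, "LdPanel"))
  if (!length(tissues)) stop("'tissues' must be non-empty", call. = FALSE)
  if (nrow(effectPlan)) {
    if (any(!is.finite(effectPlan$slope)))
      stop("planted slopes must be finite", call. = FALSE)
    badSnp <- setdiff(effectPlan$snp_id, variants(panel)$snp_id)
    badGene <- setdiff(effectPlan$gene_id, genes$gene_id)
    if (length(badSnp) || length(badGene))
      stop("planted snp/gene not in universe: ",
           paste(c(badSnp, badGene), collapse = ", "), call. = FALSE)
    if (any(!effectPlan$tissue %in% tissues))
      stop("planted tissue not in 'tissues'", call. = FALSE)
  }
  set.seed(as.integer(seed))
  nNull <- round(nullPFraction * nrow(variants(panel)))
  out <- lapply(tissues, function(tt) {
    planted <- effectPlan[effectPlan$tissue == tt, , drop = FALSE]
    pl <- if (nrow(planted)) {
      data.frame(snp_id = planted$snp_id, gene_id = planted$gene_id,
                 tissue = tt, slope = planted$slope,
                 p = stats::runif(nrow(planted), 0, altPMax))
    } else NULL
    nl <- if (nNull > 0) {
      data.frame(
        snp_id = sample(variants(panel)$snp_id, nNull, replace = TRUE),
        gene_id = sample(genes$gene_id, nNull, replace = TRUE),
        tissue = tt,
        slope = stats::rnorm(nNull, 0, 0.1),
        p = stats::runif(nNull))
    } else NULL
    tab <- rbind(pl, nl)
    rownames(tab) <- NULL
    tab
  })
  names(out) <- tissues
  out
}
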