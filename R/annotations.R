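## Annotation construction: specificity ranking, window expansion to
## binary SNP annotations, eQTL tissue assignment, co-expression module
## labeling, ortholog mapping and gene-set annotations. Everything here
## is deterministic: no randomness enters an annotation.

#' Tissue-specificity t-statistics with category-aware comparison groups
#'
#' For each gene and tissue, computes the Welch two-sample t-statistic of
#' the gene's expression in that tissue's samples versus samples from all
#' tissues in a *different* tissue category (so, e.g., one brain region
#' is never compared against other brain regions). Genes are then ranked
#' per tissue by this score.
#'
#' @param expr gene x sample expression matrix.
#' @param sampleTissue character vector, one tissue label per column of
#'   `expr`; every tissue needs at least 2 samples.
#' @param tissueCategories named character vector mapping each tissue to
#'   its category (tissues in the same category are excluded from each
#'   other's comparison group).
#' @return gene x tissue matrix of t-statistics; entries where a variance
#'   is degenerate (zero in both groups) are `NA`.
#' @export
tissueSpecificityTstat <- function(expr, sampleTissue, tissueCategories) {
  tissues <- unique(sampleTissue)
  if (length(sampleTissue) != ncol(expr))
    stop("one tissue label per sample column is required", call. = FALSE)
  if (!all(tissues %in% names(tissueCategories)))
    stop("'tissueCategories' must cover every tissue", call. = FALSE)
  cnt <- table(sampleTissue)
  if (any(cnt < 2))
    stop("every tissue needs >= 2 samples; offending: ",
         paste(names(cnt)[cnt < 2], collapse = ", "), call. = FALSE)

  out <- matrix(NA_real_, nrow(expr), length(tissues),
                dimnames = list(rownames(expr), tissues))
  for (tt in tissues) {
    in1 <- sampleTissue == tt
    cat1 <- tissueCategories[[tt]]
    in2 <- tissueCategories[sampleTissue] != cat1
    if (!any(in2))
      stop(sprintf(
        "tissue '%s': exclusion set removes all comparison tissues", tt),
        call. = FALSE)
    n1 <- sum(in1); n2 <- sum(in2)
    m1 <- rowMeans(expr[, in1, drop = FALSE])
    m2 <- rowMeans(expr[, in2, drop = FALSE])
    v1 <- apply(expr[, in1, drop = FALSE], 1, stats::var)
    v2 <- apply(expr[, in2, drop = FALSE], 1, stats::var)
    se <- sqrt(v1 / n1 + v2 / n2)
    tstat <- ifelse(se > 0, (m1 - m2) / se,
                    ifelse(m1 == m2, 0, NA_real_))
    out[, tt] <- tstat
  }
  out
}

#' Select the top fraction of genes by score
#'
#' Returns the `ceiling(fraction * n)` highest-scoring genes. Ties at the
#' cutoff are broken deterministically by lexicographic gene id. Genes
#' with missing scores are ignored; an all-missing input is an error.
#'
#' @param scores named numeric vector of per-gene scores for one group.
#' @param fraction proportion in (0, 1]; the field default is 0.1 (the
#'   top decile).
#' @return Character vector of selected gene ids.
#' @export
topFractionGenes <- function(scores, fraction = 0.1) {
  if (!length(scores)) stop("'scores' is empty", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  scores <- scores[!is.na(scores)]
  if (!length(scores))
    stop("all scores are missing", call. = FALSE)
  k <- ceiling(fraction * length(scores))
  ord <- order(-scores, names(scores))
  names(scores)[ord[seq_len(k)]]
}

#' Binary SNP annotation from a gene set with a flanking window
#'
#' A SNP is scored 1 iff its position lies within
#' `[tx_start - window, tx_end + window]` of at least one gene in the set
#' on the same chromosome (strand-independent; overlapping windows count
#' once). Callers are expected to have pre-filtered `variants` to common
#' SNPs (MAF > 5%) when building heritability annotations.
#'
#' @param genes a [geneTable()] subset (the gene set, with coordinates).
#' @param variants a [variantTable()].
#' @param window flanking window in bp on each side; default 100000.
#' @param label category name for the returned column.
#' @return Named list with `column` (integer 0/1 vector over variants,
#'   named by snp_id) and `label`.
#' @export
genesToSnpAnnotation <- function(genes, variants, window = 100000,
                                 label = "geneset") {
  vgr <- .variantsAsGRanges(variants)
  ggr <- .genesAsGRanges(genes)
  wins <- suppressWarnings(
    GenomicRanges::trim(ggr + window))  # +window on both flanks, clip at 1
  hit <- GenomicRanges::countOverlaps(vgr, wins) > 0L
  column <- as.integer(hit)
  names(column) <- variants$snp_id
  list(column = column, label = label)
}

#' Cell-type fold-enrichment scores
#'
#' Enrichment of gene g in cell type c is the gene's mean expression in c
#' divided by its average expression across all *other* cell types. Genes
#' failing the detection rule -- `"fpkm_ge_1"` (>= 1 in at least one cell
#' type; the bulk convention) or `"gt_0"` (> 0 in at least one cell type;
#' the single-cell convention) -- are dropped before scoring. A
#' pseudocount of 1e-9 is added to the denominator so genes exclusively
#' expressed in one cell type rank above any finite competitor instead of
#' erroring.
#'
#' @param meanExpr nonnegative gene x cell-type matrix of mean expression
#'   (>= 2 cell types).
#' @param detectionRule `"fpkm_ge_1"` or `"gt_0"`.
#' @return gene x cell-type enrichment matrix over the retained genes.
#' @export
celltypeEnrichmentScores <- function(meanExpr,
                                     detectionRule = c("fpkm_ge_1",
                                                       "gt_0")) {
  detectionRule <- match.arg(detectionRule)
  if (ncol(meanExpr) < 2)
    stop("need >= 2 cell types to define 'all other cell types'",
         call. = FALSE)
  if (any(meanExpr < 0))
    stop("expression must be nonnegative", call. = FALSE)
  keep <- switch(detectionRule,
                 fpkm_ge_1 = apply(meanExpr, 1, max) >= 1,
                 gt_0 = apply(meanExpr, 1, max) > 0)
  x <- meanExpr[keep, , drop = FALSE]
  k <- ncol(x)
  tot <- rowSums(x)
  otherMean <- (tot - x) / (k - 1)  # per-column mean over the others
  x / (otherMean + 1e-9)
}

#' Map genes through a one-to-one ortholog table
#'
#' Keeps only one-to-one pairs of the mapping (source genes with several
#' targets, and duplicated rows' conflicts, are dropped from the usable
#' map). Input genes without a usable mapping are reported, never
#' silently dropped.
#'
#' @param genes character vector of source gene ids.
#' @param mapping two-column data.frame: source id, target id.
#' @return List with `mapped` (character vector of target ids, named by
#'   source) and `unmapped` (data.frame of source ids with a `reason`,
#'   either `"one-to-many"` or `"absent"`).
#' @export
mapOrthologs <- function(genes, mapping) {
  if (!nrow(mapping)) stop("empty ortholog mapping", call. = FALSE)
  mapping <- unique(mapping[, 1:2])
  names(mapping) <- c("source", "target")
  multi <- unique(mapping$source[duplicated(mapping$source)])
  usable <- mapping[!mapping$source %in% multi, , drop = FALSE]
  if (length(multi))
    .msg("dropping %d one-to-many source gene(s) from ortholog map",
         length(multi))
  tgt <- usable$target[match(genes, usable$source)]
  mappedIdx <- !is.na(tgt)
  unmapped <- data.frame(
    gene_id = genes[!mappedIdx],
    reason = ifelse(genes[!mappedIdx] %in% multi, "one-to-many", "absent"),
    stringsAsFactors = FALSE)
  mapped <- tgt[mappedIdx]
  names(mapped) <- genes[mappedIdx]
  list(mapped = mapped, unmapped = unmapped)
}

#' Per-tissue FDR filtering of eQTL tables
#'
#' Benjamini-Hochberg adjustment computed within each tissue; only
#' records with q below the threshold (the study convention is 5%) are
#' retained.
#'
#' @param tables named list of per-tissue data.frames with columns
#'   `snp_id`, `gene_id`, `tissue`, `slope`, `p`.
#' @param fdr q-value threshold; default 0.05.
#' @return The filtered list, each table gaining a `q` column.
#' @export
filterEqtls <- function(tables, fdr = 0.05) {
  lapply(tables, function(tab) {
    tab$q <- stats::p.adjust(tab$p, method = "BH")
    tab <- tab[tab$q < fdr, , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
}

#' Assign eQTL SNPs to tissues or supergroups by maximum effect size
#'
#' Two steps, on FDR-surviving records. Within each supergroup (e.g. the
#' 11 brain regions collapsed to "brain"), records sharing a SNP are
#' collapsed into one entry carrying the maximum absolute slope observed
#' across the group's tissues. Each SNP is then assigned to the single
#' supergroup where its collapsed |slope| is maximal; ties go to the
#' lexicographically first group with a logged warning. Output sets are
#' pairwise disjoint and cover every input SNP.
#'
#' @param tables named list of per-tissue eQTL data.frames (already
#'   FDR-filtered; see [filterEqtls()]).
#' @param grouping named character vector mapping tissue -> supergroup;
#'   `NULL` keeps each tissue as its own group.
#' @return Named list of character vectors: supergroup -> SNP ids.
#' @export
assignEqtlsByEffect <- function(tables, grouping = NULL) {
  if (is.null(grouping)) {
    grouping <- names(tables)
    names(grouping) <- names(tables)
  }
  if (!all(names(tables) %in% names(grouping)))
    stop("'grouping' must cover every tissue table", call. = FALSE)
  all <- do.call(rbind, lapply(names(tables), function(tt) {
    tab <- tables[[tt]]
    if (!nrow(tab)) return(NULL)
    data.frame(snp_id = tab$snp_id, group = grouping[[tt]],
               abs_slope = abs(tab$slope), stringsAsFactors = FALSE)
  }))
  groups <- sort(unique(grouping))
  empty <- stats::setNames(
    rep(list(character()), length(groups)), groups)
  if (is.null(all) || !nrow(all)) return(empty)
  # step 1: collapse within (snp, group) keeping max |slope|
  agg <- stats::aggregate(abs_slope ~ snp_id + group, data = all, FUN = max)
  # step 2: per SNP, pick the group with max collapsed |slope|;
  # lexicographic order makes ties land on the first group
  agg <- agg[order(agg$snp_id, -agg$abs_slope, agg$group), , drop = FALSE]
  ties <- tapply(agg$abs_slope, agg$snp_id,
                 function(v) length(v) > 1 && v[1] == v[2])
  if (any(unlist(ties)))
    warning("effect-size ties broken toward the lexicographically first ",
            "group for SNP(s): ",
            paste(names(ties)[unlist(ties)], collapse = ", "),
            call. = FALSE)
  best <- agg[!duplicated(agg$snp_id), , drop = FALSE]
  out <- empty
  sp <- split(best$snp_id, best$group)
  out[names(sp)] <- lapply(sp, sort)
  out
}

#' Label co-expression modules with a cell type by marker enrichment
#'
#' For each (module, cell class) pair, the hypergeometric upper-tail
#' probability of the observed overlap between the module's genes and the
#' class's marker list, given the universe. A module is labeled with a
#' class iff that class is the *unique* class reaching Bonferroni
#' -corrected p < `alpha` across the classes tested for that module
#' ("predominantly one cell type"); otherwise it stays unlabeled.
#'
#' @param modules data.frame with columns `module_id` and `gene_id`
#'   (one row per gene-in-module).
#' @param markerLists named list: cell class -> marker gene set; each a
#'   subset of `universe`.
#' @param universe character vector, the gene universe.
#' @param alpha significance level before Bonferroni correction over
#'   classes; default 0.05.
#' @return data.frame with one row per (module, class): `module_id`,
#'   `cell_class`, `overlap`, `p`, `p_bonf`, and per-module `label`
#'   (`"unlabeled"` when no unique class wins).
#' @export
labelModuleCelltype <- function(modules, markerLists, universe,
                                alpha = 0.05) {
  badLen <- vapply(markerLists, function(s) length(s) > length(universe),
                   logical(1))
  if (any(badLen))
    stop("marker list(s) larger than the universe: ",
         paste(names(markerLists)[badLen], collapse = ", "), call. = FALSE)
  notin <- vapply(markerLists, function(s) any(!s %in% universe),
                  logical(1))
  if (any(notin))
    stop("marker list(s) not a subset of the universe: ",
         paste(names(markerLists)[notin], collapse = ", "), call. = FALSE)
  N <- length(universe)
  nClass <- length(markerLists)
  rows <- list()
  for (mod in unique(modules$module_id)) {
    mg <- intersect(unique(modules$gene_id[modules$module_id == mod]),
                    universe)
    n <- length(mg)
    for (cls in names(markerLists)) {
      K <- length(markerLists[[cls]])
      k <- length(intersect(mg, markerLists[[cls]]))
      # upper tail: P(overlap >= k)
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = mod, cell_class = cls, overlap = k, p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_bonf <- pmin(res$p * nClass, 1)
  lab <- vapply(split(res, res$module_id), function(d) {
    sig <- d$cell_class[d$p_bonf < alpha]
    if (length(sig) == 1L) sig else "unlabeled"
  }, character(1))
  res$label <- lab[res$module_id]
  rownames(res) <- NULL
  res
}

#' Select module genes contributing to cell-type annotations
#'
#' Applies the module filters: a gene contributes to a cell-type
#' annotation only if its module membership (kME) is >= 0.5, its module's
#' preservation Z-summary exceeds 2, and the module carries a cell-type
#' label (see [labelModuleCelltype()]).
#'
#' @param moduleRecords data.frame with columns `module_id`, `tissue`,
#'   `gene_id`, `module_membership`, `preservation_z`, `cell_label`.
#' @param kmeMin minimum module membership; default 0.5.
#' @param preservationMin minimum preservation Z-summary (exclusive);
#'   default 2.
#' @return Named list: cell label -> gene ids.
#' @export
moduleCelltypeGenes <- function(moduleRecords, kmeMin = 0.5,
                                preservationMin = 2) {
  keep <- moduleRecords$module_membership >= kmeMin &
    moduleRecords$preservation_z > preservationMin &
    moduleRecords$cell_label != "unlabeled"
  d <- moduleRecords[keep, , drop = FALSE]
  lapply(split(d$gene_id, d$cell_label), function(g) sort(unique(g)))
}

#' Binary SNP annotation from a curated gene set
#'
#' Resolves the ids against the gene coordinate table (unresolved ids
#' are reported with a message) and delegates to
#' [genesToSnpAnnotation()] with the standard 100 kb window. Zero
#' resolvable genes is an error, never an all-zero column.
#'
#' @param geneSet character vector of gene ids.
#' @param genes a [geneTable()].
#' @param variants a [variantTable()].
#' @param window flanking window in bp; default 100000.
#' @param label category name.
#' @return As [genesToSnpAnnotation()], plus `unresolved` gene ids.
#' @export
buildGenesetAnnotation <- function(geneSet, genes, variants,
                                   window = 100000, label = "geneset") {
  if (!length(geneSet)) stop("empty gene set", call. = FALSE)
  unresolved <- setdiff(geneSet, genes$gene_id)
  resolved <- genes[genes$gene_id %in% geneSet, , drop = FALSE]
  if (!nrow(resolved))
    stop("no gene of the set resolves against the gene table",
         call. = FALSE)
  if (length(unresolved))
    .msg("%d gene id(s) of set '%s' not in the gene table",
         length(unresolved), label)
  ann <- genesToSnpAnnotation(resolved, variants, window = window,
                              label = label)
  ann$unresolved <- unresolved
  ann
}
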