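## File dialects: variants and annot tables in the ldsc layout, sumstats
## (SNP A1 A2 Z N), gene x group expression TSV, per-tissue eQTL TSV,
## per-category LD-score TSV, GMT gene sets and audit BED. Every writer
## emits a sidecar provenance record (JSON) with the parameters that
## produced the file.

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.writeProvenance <- function(path, params) {
  jsonlite::write_json(
    c(list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), params),
    paste0(path, ".prov.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a variant table (ldsc variant dialect)
#'
#' Columns `CHR`, `BP` (1-based), `SNP`, `A1`, `A2`, `MAF`.
#'
#' @param variants a [variantTable()].
#' @param path output TSV path.
#' @param provenance named list recorded in the sidecar `.prov.json`.
#' @return `writeVariantTable` the path, invisibly; `readVariantTable`
#'   the variant table.
#' @export
writeVariantTable <- function(variants, path, provenance = list()) {
  d <- data.frame(CHR = variants$chromosome, BP = variants$position,
                  SNP = variants$snp_id, A1 = variants$a1,
                  A2 = variants$a2, MAF = variants$maf)
  .writeTsv(d, path)
  .writeProvenance(path, provenance)
}

#' @rdname writeVariantTable
#' @export
readVariantTable <- function(path) {
  d <- utils::read.delim(path, colClasses = c(CHR = "character"))
  variantTable(data.frame(
    snp_id = d$SNP, chromosome = d$CHR, position = d$BP, a1 = d$A1,
    a2 = d$A2, maf = d$MAF, stringsAsFactors = FALSE))
}

#' Write / read GWAS summary statistics (sumstats dialect)
#'
#' Columns `SNP`, `A1`, `A2`, `Z`, `N`. Alleles are taken from the
#' accompanying variant table on write.
#'
#' @param sumstats a [SumStats-class].
#' @param variants the matching [variantTable()] (for alleles).
#' @param path TSV path.
#' @param provenance named list for the sidecar record.
#' @param trait trait label attached on read.
#' @return The path (write, invisibly) or a [SumStats-class] (read).
#' @export
writeSumStats <- function(sumstats, variants, path, provenance = list()) {
  stopifnot(identical(sumstats@snp, variants$snp_id))
  d <- data.frame(SNP = sumstats@snp, A1 = variants$a1,
                  A2 = variants$a2, Z = sumstats@z,
                  N = if (length(sumstats@n) == 1L)
                    rep(sumstats@n, length(sumstats@snp)) else sumstats@n)
  .writeTsv(d, path)
  .writeProvenance(path, provenance)
}

#' @rdname writeSumStats
#' @export
readSumStats <- function(path, trait = "trait") {
  d <- utils::read.delim(path)
  n <- if (length(unique(d$N)) == 1L) d$N[1] else d$N
  sumStats(d$SNP, z = d$Z, n = n, trait = trait)
}

#' Write / read an annotation matrix (ldsc annot dialect)
#'
#' Columns `CHR`, `BP`, `SNP`, `CM` (written as 0; no genetic map is
#' used), then one binary column per category.
#'
#' @param annot an [AnnotationMatrix-class].
#' @param path TSV path.
#' @param provenance named list for the sidecar record.
#' @param variants on read, an optional [variantTable()] supplying
#'   alleles/MAF (the annot dialect does not carry them; placeholder
#'   alleles and MAF 0.25 are used when absent).
#' @return The path (write, invisibly) or an [AnnotationMatrix-class]
#'   (read).
#' @export
writeAnnotMatrix <- function(annot, path, provenance = list()) {
  v <- variants(annot)
  d <- cbind(data.frame(CHR = v$chromosome, BP = v$position,
                        SNP = v$snp_id, CM = 0),
             as.data.frame(membership(annot)))
  .writeTsv(d, path)
  .writeProvenance(path, provenance)
}

#' @rdname writeAnnotMatrix
#' @export
readAnnotMatrix <- function(path, variants = NULL) {
  d <- utils::read.delim(path, colClasses = c(CHR = "character"),
                         check.names = FALSE)
  cats <- setdiff(colnames(d), c("CHR", "BP", "SNP", "CM"))
  if (is.null(variants)) {
    variants <- variantTable(data.frame(
      snp_id = d$SNP, chromosome = d$CHR, position = d$BP, a1 = "A",
      a2 = "G", maf = 0.25, stringsAsFactors = FALSE))
  }
  stopifnot(identical(variants$snp_id, d$SNP))
  annotationMatrix(variants, as.matrix(d[, cats, drop = FALSE]))
}

#' Write / read an LD-score table
#'
#' Columns `SNP`, then one `L2` column per category, then `BASE_L2`
#' (the total LD score used for weighting).
#'
#' @param ldscores an [LdScoreTable-class].
#' @param path TSV path.
#' @param provenance named list for the sidecar record.
#' @return The path (write, invisibly) or an [LdScoreTable-class] (read).
#' @export
writeLdScoreTable <- function(ldscores, path, provenance = list()) {
  d <- cbind(data.frame(SNP = ldscores@snp),
             as.data.frame(ldScores(ldscores)),
             BASE_L2 = totalLd(ldscores))
  .writeTsv(d, path)
  .writeProvenance(path, c(provenance, list(window = ldscores@window,
                                            adjusted = ldscores@adjusted)))
}

#' @rdname writeLdScoreTable
#' @export
readLdScoreTable <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  prov <- paste0(path, ".prov.json")
  meta <- if (file.exists(prov)) jsonlite::read_json(prov) else list()
  cats <- setdiff(colnames(d), c("SNP", "BASE_L2"))
  scores <- as.matrix(d[, cats, drop = FALSE])
  rownames(scores) <- as.character(d$SNP)
  new("LdScoreTable", snp = as.character(d$SNP),
      scores = scores,
      totalLd = d$BASE_L2,
      window = as.numeric(meta$window %||% NA_real_),
      adjusted = isTRUE(meta$adjusted))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a gene x group expression matrix
#'
#' TSV with a `gene_id` first column and one column per group.
#'
#' @param expr gene x group matrix with rownames.
#' @param path TSV path.
#' @param provenance named list for the sidecar record.
#' @return The path (write, invisibly) or the matrix (read).
#' @export
writeExpressionMatrix <- function(expr, path, provenance = list()) {
  d <- cbind(data.frame(gene_id = rownames(expr)), as.data.frame(expr))
  .writeTsv(d, path)
  .writeProvenance(path, provenance)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  m
}

#' Write / read per-tissue eQTL tables
#'
#' One TSV per tissue (`<prefix>.<tissue>.tsv`) with columns `SNP`,
#' `GENE`, `SLOPE`, `P` (and `Q` when present).
#'
#' @param tables named list of per-tissue data.frames (see
#'   [simulateEqtlTables()]).
#' @param prefix file path prefix.
#' @param provenance named list for the sidecar records.
#' @return Paths written (invisibly) / the named list (read).
#' @export
writeEqtlTables <- function(tables, prefix, provenance = list()) {
  paths <- vapply(names(tables), function(tt) {
    tab <- tables[[tt]]
    d <- data.frame(SNP = tab$snp_id, GENE = tab$gene_id,
                    SLOPE = tab$slope, P = tab$p)
    if (!is.null(tab$q)) d$Q <- tab$q
    path <- sprintf("%s.%s.tsv", prefix, tt)
    .writeTsv(d, path)
    .writeProvenance(path, c(provenance, list(tissue = tt)))
    path
  }, character(1))
  invisible(paths)
}

#' @rdname writeEqtlTables
#' @export
readEqtlTables <- function(prefix, tissues) {
  out <- lapply(tissues, function(tt) {
    d <- utils::read.delim(sprintf("%s.%s.tsv", prefix, tt))
    tab <- data.frame(snp_id = d$SNP, gene_id = d$GENE, tissue = tt,
                      slope = d$SLOPE, p = d$P, stringsAsFactors = FALSE)
    if (!is.null(d$Q)) tab$q <- d$Q
    tab
  })
  names(out) <- tissues
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1),
    USE.NAMES = FALSE)
  out
}

#' Write annotation intervals as BED for audit
#'
#' Expanded gene windows in BED convention (0-based, half-open); the
#' package's tables are 1-based inclusive, converted here at the
#' boundary.
#'
#' @param windows data.frame with `chromosome`, `start`, `end` and a
#'   name column (`gene_id`).
#' @param path BED path.
#' @return The path, invisibly.
#' @export
writeBed <- function(windows, path) {
  d <- data.frame(chrom = windows$chromosome,
                  chromStart = windows$start - 1L,  # to 0-based half-open
                  chromEnd = windows$end,
                  name = windows$gene_id)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-trait stratified-regression results table
#'
#' Columns `Category`, `tau`, `se`, `z`, `coefficient_p`, `prop_snps`,
#' `prop_h2`, `enrichment`, `weighting`.
#'
#' @param fit an [LdscFit-class].
#' @param partition output of [partitionHeritability()].
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
writeResultsTable <- function(fit, partition, path) {
  ct <- coefTable(fit)
  d <- data.frame(Category = ct$category, tau = ct$tau, se = ct$se,
                  z = ct$z, coefficient_p = ct$coefficient_p,
                  prop_snps = partition$prop_snps,
                  prop_h2 = partition$prop_h2,
                  enrichment = partition$enrichment,
                  weighting = fit@weighting)
  .writeTsv(d, path)
}
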