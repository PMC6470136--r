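#' MHC interval used for exclusion (GRCh37)
#'
#' The extended major histocompatibility complex region,
#' chr6:25,500,000-33,500,000 on GRCh37, excluded from annotations and
#' gene-level tests because of its complex long-range LD.
#'
#' @return A `GRanges` of length one.
#' @export
#' @examples
#' mhcInterval()
mhcInterval <- function() {
  GenomicRanges::GRanges("6", IRanges::IRanges(25500000L, 33500000L))
}

## internal scalar checks -----------------------------------------------------

.checkCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

.checkFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  x
}

.msg <- function(...) message("[cellHerit] ", sprintf(...))

## Construct a validated variant table (the SNP universe).

#' Validate and order a variant table
#'
#' The SNP universe over which annotations, LD scores and regressions are
#' defined. Columns: `snp_id`, `chromosome`, `position` (1-based bp),
#' `a1`, `a2`, `maf`. Rows are sorted by chromosome then position and
#' `snp_id` must be unique; `maf` must lie in (0, 0.5].
#'
#' @param x data.frame with the columns above.
#' @return The validated, sorted data.frame.
#' @export
variantTable <- function(x) {
  need <- c("snp_id", "chromosome", "position", "a1", "a2", "maf")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("variant table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$snp_id))
    stop("variant table has duplicated snp_id", call. = FALSE)
  if (any(x$maf <= 0 | x$maf > 0.5))
    stop("variant maf must lie in (0, 0.5]", call. = FALSE)
  x <- x[order(x$chromosome, x$position), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Validate a gene coordinate table
#'
#' Columns: `gene_id`, `chromosome`, `tx_start`, `tx_end` (1-based,
#' inclusive) and `strand` ("+", "-", or `NA` when unknown).
#'
#' @param x data.frame with the columns above.
#' @return The validated data.frame.
#' @export
geneTable <- function(x) {
  need <- c("gene_id", "chromosome", "tx_start", "tx_end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("gene table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$gene_id))
    stop("gene table has duplicated gene_id", call. = FALSE)
  if (any(x$tx_start > x$tx_end))
    stop("gene table has tx_start > tx_end", call. = FALSE)
  x
}

## GRanges views of the tabular inputs (internal; input tables stay 1-based
## inclusive, which is also what IRanges uses natively).

.variantsAsGRanges <- function(variants) {
  GenomicRanges::GRanges(
    as.character(variants$chromosome),
    IRanges::IRanges(variants$position, width = 1L),
    snp_id = variants$snp_id
  )
}

.genesAsGRanges <- function(genes) {
  GenomicRanges::GRanges(
    as.character(genes$chromosome),
    IRanges::IRanges(genes$tx_start, genes$tx_end),
    gene_id = genes$gene_id
  )
}

#' Filter a variant table on MAF and MHC exclusion
#'
#' Applies the common-variant filter (minor allele frequency above
#' `mafMin`, default 5%) and removes variants inside the MHC interval.
#'
#' @param variants a [variantTable()].
#' @param mafMin minimum MAF (exclusive); default 0.05.
#' @param mhc `GRanges` to exclude, default [mhcInterval()]; `NULL` skips
#'   the positional exclusion.
#' @return The filtered variant table.
#' @export
filterVariants <- function(variants, mafMin = 0.05, mhc = mhcInterval()) {
  keep <- variants$maf > mafMin
  if (!is.null(mhc)) {
    gr <- .variantsAsGRanges(variants)
    # suppress the no-common-seqlevels note when chromosomes disjoint
    hit <- suppressWarnings(GenomicRanges::countOverlaps(gr, mhc)) > 0L
    keep <- keep & !hit
  }
  variants[keep, , drop = FALSE]
}
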