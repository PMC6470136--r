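# Shared fixtures, all built in code. Small enough to regenerate freely.

# toy variant universe on one chromosome, evenly spaced
toyVariants <- function(n = 10, chromosome = "1", start = 1e5,
                        spacing = 1e5, maf = 0.25) {
  variantTable(data.frame(
    snp_id = sprintf("snp%03d", seq_len(n)),
    chromosome = chromosome,
    position = start + (seq_len(n) - 1L) * spacing,
    a1 = "A", a2 = "G", maf = maf, stringsAsFactors = FALSE))
}

toyGenes <- function() {
  geneTable(data.frame(
    gene_id = c("gA", "gB", "gC"),
    chromosome = c("1", "1", "2"),
    tx_start = c(1000000L, 5000000L, 1000000L),
    tx_end = c(1010000L, 5002000L, 1050000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE))
}

# small panel + annotation + LD scores reused by regression tests
smallPanelFixture <- function(seed = 42) {
  panel <- simulateLdPanel(200, nBlocks = 8, blockSize = 15, rho = 0.4,
                           seed = seed)
  v <- variants(panel)
  set.seed(seed + 1)
  annot <- annotationMatrix(v, list(
    base_all = rep(1L, nrow(v)),
    testcat = as.integer(blockIndex(panel) <= 4)))
  list(panel = panel, annot = annot,
       ldscores = computeLdScores(panel, annot))
}

# brute-force O(m^2) LD-score oracle: independent of the windowed path
bruteLdScores <- function(panel, annot, window = 1e6, adjust = FALSE) {
  g <- genotypes(panel)
  v <- variants(panel)
  n <- nrow(g)
  r2 <- cor(g)^2
  if (adjust) r2 <- r2 - (1 - r2) / (n - 2)
  inWin <- abs(outer(v$position, v$position, "-")) <= window &
    outer(v$chromosome, v$chromosome, "==")
  out <- (r2 * inWin) %*% membership(annot)
  rownames(out) <- v$snp_id
  out
}
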