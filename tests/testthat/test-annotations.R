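# Annotation construction: specificity ranking, windows, eQTL
# assignment, module labeling, ortholog mapping, gene sets.

test_that("tissue-specificity t-statistics match a Welch oracle", {
  set.seed(1)
  # 3 tissues x 4 samples, planted 5-fold marker in tissue A
  expr <- matrix(rlnorm(20 * 12, log(5), 0.4), 20, 12)
  rownames(expr) <- sprintf("g%02d", 1:20)
  tis <- rep(c("A", "B", "C"), each = 4)
  expr[1, tis == "A"] <- expr[1, tis == "A"] * 5
  cats <- c(A = "catA", B = "catB", C = "catC")
  ts <- tissueSpecificityTstat(expr, tis, cats)
  # independent oracle: stats::t.test Welch flavor, gene by gene
  for (g in c(1, 2, 7)) {
    or <- t.test(expr[g, tis == "A"], expr[g, tis != "A"])$statistic
    expect_equal(unname(ts[g, "A"]), unname(or), tolerance = 1e-10)
  }
  # planted marker ranks top in its tissue
  expect_identical(names(which.max(ts[, "A"])), "g01")
})

test_that("category exclusion and degenerate variances are handled", {
  expr <- rbind(flat = rep(3, 6),
                zv = c(10, 10, 0, 0, 0, 0),
                ok = c(1, 2, 3, 4, 5, 6))
  tis <- c("A", "A", "B", "B", "C", "C")
  ts <- tissueSpecificityTstat(expr, tis,
                               c(A = "x", B = "y", C = "z"))
  expect_equal(unname(ts["flat", ]), c(0, 0, 0))  # zero mean difference
  expect_true(is.na(ts["zv", "A"]))  # zero-variance guard, not +/- Inf
  # exclusion set that removes every comparison tissue is refused
  expect_error(
    tissueSpecificityTstat(expr, tis, c(A = "x", B = "x", C = "x")),
    "exclusion")
})

test_that("top-fraction selection uses the ceiling and id tie-breaks", {
  s <- setNames(seq(20, 1), sprintf("g%02d", 1:20))
  expect_identical(topFractionGenes(s, 0.1), c("g01", "g02"))
  # all-equal scores: exactly ceil(0.1*10) = 1, lexicographically first
  eq <- setNames(rep(1, 10), sprintf("g%02d", 10:1))
  expect_identical(topFractionGenes(eq, 0.1), "g01")
  # fraction 1.0 is the identity, and reapplication is idempotent
  allg <- topFractionGenes(s, 1.0)
  expect_setequal(allg, names(s))
  expect_setequal(topFractionGenes(s[allg], 1.0), allg)
  expect_error(topFractionGenes(setNames(NA_real_, "g"), 0.5), "missing")
})

test_that("gene windows expand to binary SNP annotations correctly", {
  genes <- geneTable(data.frame(
    gene_id = "g1", chromosome = "1", tx_start = 1000000L,
    tx_end = 1010000L, strand = "+"))
  v <- variantTable(data.frame(
    snp_id = c("in_up", "out_down", "far"),
    chromosome = "1",
    position = c(905000L, 1110001L, 5000000L),
    a1 = "A", a2 = "G", maf = 0.3))
  col <- genesToSnpAnnotation(genes, v, window = 100000)$column
  expect_identical(col[["in_up"]], 1L)    # 95 kb upstream: inside
  expect_identical(col[["out_down"]], 0L) # 1 bp beyond the window
  expect_identical(col[["far"]], 0L)
  # overlapping windows from two genes still produce a binary union
  genes2 <- geneTable(data.frame(
    gene_id = c("g1", "g2"), chromosome = "1",
    tx_start = c(1000000L, 1005000L), tx_end = c(1010000L, 1015000L),
    strand = c("+", "-")))
  col2 <- genesToSnpAnnotation(genes2, v, window = 100000)$column
  expect_identical(col2[["in_up"]], 1L)
  expect_true(all(col2 %in% 0:1))
})

test_that("fold enrichment handles zeros and exclusive expression", {
  m <- rbind(g1 = c(4, 1, 1), g2 = c(0, 1, 1), g3 = c(5, 0, 0),
             g4 = c(2, 2, 2))
  colnames(m) <- c("t1", "t2", "t3")
  enr <- celltypeEnrichmentScores(m, "gt_0")
  expect_equal(unname(enr["g1", "t1"]), 4, tolerance = 1e-6)
  expect_equal(unname(enr["g2", "t1"]), 0)
  # exclusive expression ranks above any finite competitor; oracle ranks
  # with an explicit +Inf for zero denominators
  oracle <- apply(m, 1, function(x) {
    o <- mean(x[-1])
    if (o == 0 && x[1] > 0) Inf else if (o == 0) 0 else x[1] / o
  })
  expect_identical(names(sort(enr[, "t1"], decreasing = TRUE)),
                   names(sort(oracle, decreasing = TRUE)))
  # detection rules drop undetected genes before scoring
  low <- rbind(lo = c(0.5, 0.2, 0.1), hi = c(3, 1, 1))
  expect_identical(rownames(celltypeEnrichmentScores(low, "fpkm_ge_1")),
                   "hi")
  expect_identical(rownames(celltypeEnrichmentScores(low, "gt_0")),
                   c("lo", "hi"))
  expect_error(celltypeEnrichmentScores(m[, 1, drop = FALSE]), "cell types")
})

test_that("ortholog mapping keeps one-to-one pairs and reports the rest", {
  map <- data.frame(src = c("m1", "m2", "m3", "m3", "m4"),
                    dst = c("H1", "H2", "H3a", "H3b", "H4"))
  res <- mapOrthologs(c("m1", "m2", "m3", "m5"), map)
  expect_identical(unname(res$mapped), c("H1", "H2"))
  expect_identical(res$unmapped$reason[res$unmapped$gene_id == "m3"],
                   "one-to-many")
  expect_identical(res$unmapped$reason[res$unmapped$gene_id == "m5"],
                   "absent")
  # mapping rows for absent sources do not affect the output
  res2 <- mapOrthologs(c("m1"), map)
  expect_identical(unname(res2$mapped), "H1")
  expect_error(mapOrthologs("m1", map[0, ]), "empty")
})

test_that("eQTL SNPs are assigned by maximum absolute slope", {
  tabs <- list(
    cortex = data.frame(snp_id = c("s1", "s2"), gene_id = "g",
                        tissue = "cortex", slope = c(0.3, 0.4),
                        p = 1e-9, q = 1e-8),
    putamen = data.frame(snp_id = "s1", gene_id = "g",
                         tissue = "putamen", slope = -0.8,
                         p = 1e-9, q = 1e-8),
    blood = data.frame(snp_id = "s2", gene_id = "g", tissue = "blood",
                       slope = 0.6, p = 1e-9, q = 1e-8))
  grouping <- c(cortex = "brain", putamen = "brain", blood = "blood")
  sets <- assignEqtlsByEffect(tabs, grouping)
  # s1: brain collapses to |-0.8| > absent blood -> brain
  expect_true("s1" %in% sets$brain)
  # s2: blood 0.6 beats brain 0.4
  expect_true("s2" %in% sets$blood)
  # disjoint and exhaustive over FDR-surviving SNPs
  expect_length(intersect(sets$brain, sets$blood), 0)
  expect_setequal(unlist(sets), c("s1", "s2"))

  # singleton tissue keeps its SNP whatever the slope
  one <- assignEqtlsByEffect(list(
    amygdala = data.frame(snp_id = "s9", gene_id = "g",
                          tissue = "amygdala", slope = 0,
                          p = 1e-9, q = 1e-8)))
  expect_identical(one$amygdala, "s9")

  # exact tie: lexicographically first group wins, with a warning
  tie <- list(
    a_t = data.frame(snp_id = "s1", gene_id = "g", tissue = "a_t",
                     slope = 0.5, p = 1e-9, q = 1e-8),
    b_t = data.frame(snp_id = "s1", gene_id = "g", tissue = "b_t",
                     slope = -0.5, p = 1e-9, q = 1e-8))
  expect_warning(res <- assignEqtlsByEffect(tie), "tie")
  expect_identical(res$a_t, "s1")
  expect_length(res$b_t, 0)
})

test_that("module labeling follows the hypergeometric uniqueness rule", {
  universe <- sprintf("u%04d", 1:1000)
  markers <- list(neuron = universe[1:20], microglia = universe[21:60])
  mod <- data.frame(module_id = "blue",
                    gene_id = c(universe[1:5], universe[500:504]))
  res <- labelModuleCelltype(mod, markers, universe)
  # combinatorial oracle: upper-tail mass by explicit enumeration
  N <- 1000; K <- 20; n <- 10
  oracle <- sum(sapply(5:min(K, n), function(k)
    choose(K, k) * choose(N - K, n - k))) / choose(N, n)
  got <- res$p[res$cell_class == "neuron"]
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_identical(unique(res$label), "neuron")
  # zero overlap: upper-tail p = 1
  mod0 <- data.frame(module_id = "grey", gene_id = universe[900:909])
  res0 <- labelModuleCelltype(mod0, markers["neuron"], universe)
  expect_equal(res0$p, 1)
  # two Bonferroni-significant classes -> unlabeled
  mod2 <- data.frame(module_id = "tan",
                     gene_id = c(universe[1:10], universe[21:30]))
  res2 <- labelModuleCelltype(mod2, markers, universe)
  expect_identical(unique(res2$label), "unlabeled")
  expect_error(labelModuleCelltype(mod, list(x = sprintf("z%d", 1:2000)),
                                   universe), "universe")
})

test_that("module gene selection applies kME and preservation filters", {
  rec <- data.frame(
    module_id = c("blue", "blue", "blue", "grey"),
    tissue = "FCTX",
    gene_id = c("g1", "g2", "g3", "g4"),
    module_membership = c(0.9, 0.5, 0.49, 0.9),
    preservation_z = c(5, 5, 5, 1.5),
    cell_label = c("neuron", "neuron", "neuron", "astrocyte"))
  sel <- moduleCelltypeGenes(rec)
  expect_identical(sel$neuron, c("g1", "g2"))  # kME >= 0.5 boundary kept
  expect_null(sel$astrocyte)  # preservation 1.5 fails > 2
})

test_that("gene-set annotations resolve ids and refuse empty sets", {
  genes <- toyGenes()
  v <- toyVariants(30, start = 900000, spacing = 10000)
  ann <- buildGenesetAnnotation(c("gA", "missing"), genes, v,
                                label = "lysosome")
  expect_identical(ann$unresolved, "missing")
  expect_gt(sum(ann$column), 0)
  expect_error(buildGenesetAnnotation(character(), genes, v), "empty")
  expect_error(buildGenesetAnnotation(c("nope1", "nope2"), genes, v),
               "resolves")
  # pLI-style threshold at a >= boundary is the caller's filter; the
  # "all genes" set covers every in-window SNP
  pli <- c(gA = 0.90, gB = 0.8999)
  keep <- names(pli)[pli >= 0.9]
  expect_identical(keep, "gA")
  allAnn <- buildGenesetAnnotation(genes$gene_id, genes, v)
  aColumn <- genesToSnpAnnotation(genes, v)$column
  expect_identical(allAnn$column, aColumn)
})

test_that("variant filtering enforces MAF floor and MHC exclusion", {
  v <- variantTable(data.frame(
    snp_id = c("common", "rare", "mhc"),
    chromosome = c("1", "1", "6"),
    position = c(1e6, 2e6, 26e6),
    a1 = "A", a2 = "G", maf = c(0.3, 0.04, 0.3)))
  f <- filterVariants(v)
  expect_identical(f$snp_id, "common")
  # maf exactly at the floor is excluded (strict > 5%)
  v2 <- variantTable(data.frame(
    snp_id = "edge", chromosome = "1", position = 1e6, a1 = "A",
    a2 = "G", maf = 0.05))
  expect_identical(nrow(filterVariants(v2)), 0L)
})

test_that("annotation columns are binary and deterministic", {
  genes <- toyGenes()
  v <- toyVariants(50, start = 500000, spacing = 20000)
  c1 <- genesToSnpAnnotation(genes, v)$column
  c2 <- genesToSnpAnnotation(genes, v)$column
  expect_identical(c1, c2)
  expect_true(all(c1 %in% 0:1))
  am <- annotationMatrix(v, list(w = c1))
  expect_identical(unname(membership(am)[, "w"]), unname(c1))
  expect_warning(annotationMatrix(v, list(none = rep(0L, 50))), "empty")
})
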