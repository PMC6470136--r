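# Stratified LD-score regression: LD-score computation against the
# brute-force oracle, exact recovery on noiseless data, jackknife
# behaviour, partitioning, thresholds.

test_that("LD scores handle isolated and perfectly correlated SNPs", {
  # two perfectly correlated SNPs in-window, one isolated SNP far away
  g <- cbind(a = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0) + 0,
             b = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0) + 0,
             c = c(2, 0, 1, 1, 2, 0, 1, 0, 2, 1) + 0)
  g <- g[rep(1:10, 5), ]  # 50 individuals
  v <- variantTable(data.frame(
    snp_id = c("a", "b", "c"), chromosome = "1",
    position = c(1000L, 2000L, 5000000L), a1 = "A", a2 = "G",
    maf = c(0.45, 0.45, 0.45)))
  colnames(g) <- v$snp_id
  panel <- new("LdPanel", genotypes = g, variants = v,
               blockIndex = c(1L, 1L, 2L), nIndividuals = 50L)
  annot <- annotationMatrix(v, list(C = c(1L, 1L, 1L)))
  lt <- computeLdScores(panel, annot, window = 1e6)
  # a and b: self (1) + the perfect partner (1) = 2; c isolated: 1
  expect_equal(unname(ldScores(lt)[, "C"]), c(2, 2, 1), tolerance = 1e-12)
  # adjusted self-r2 stays exactly 1
  lta <- computeLdScores(panel, annot, window = 1e6, adjust = TRUE)
  expect_equal(unname(ldScores(lta)["c", "C"]), 1, tolerance = 1e-12)
})

test_that("windowed LD scores equal the O(m^2) brute-force oracle", {
  for (s in 1:3) {
    panel <- simulateLdPanel(80, nBlocks = 5, blockSize = 40,
                             rho = 0.6, seed = s)
    v <- variants(panel)
    set.seed(s)
    annot <- annotationMatrix(v, list(
      all = rep(1L, nrow(v)),
      sub = as.integer(runif(nrow(v)) < 0.4)))
    for (adj in c(FALSE, TRUE)) {
      lt <- computeLdScores(panel, annot, window = 1.5e6, adjust = adj)
      bf <- bruteLdScores(panel, annot, window = 1.5e6, adjust = adj)
      expect_lt(max(abs(ldScores(lt) - bf)), 1e-10)
    }
  }
})

test_that("subset categories never exceed the all-SNPs LD score", {
  fx <- smallPanelFixture()
  L <- ldScores(fx$ldscores)
  expect_true(all(L[, "testcat"] <= L[, "base_all"] + 1e-12))
  expect_true(all(L >= 0))
})

test_that("noiseless data is recovered exactly by OLS", {
  fx <- smallPanelFixture()
  lt <- fx$ldscores
  N <- 1e4
  tau <- 3e-6
  y <- 1 + N * tau * ldScores(lt)[, "base_all"]
  ss <- sumStats(lt@snp, chi2 = y, n = N)
  one <- new("LdScoreTable", snp = lt@snp,
             scores = ldScores(lt)[, "base_all", drop = FALSE],
             totalLd = totalLd(lt), window = lt@window,
             adjusted = FALSE)
  fit <- fitStratified(ss, one, nBlocks = 10, weighting = "ols")
  expect_equal(fit@tau, tau, tolerance = 1e-10)
  expect_equal(fit@intercept, 1, tolerance = 1e-10)
  # exact fit: jackknife SE collapses to ~0
  expect_lt(fit@se, 1e-12)
})

test_that("one-tailed coefficient p follows the normal upper tail", {
  expect_equal(pnorm(0, lower.tail = FALSE), 0.5)
  expect_equal(pnorm(-2, lower.tail = FALSE), 0.9772, tolerance = 1e-4)
  # and the fit reports exactly that transform of z
  fx <- smallPanelFixture()
  truth <- simTruth(c(base_all = 1e-6, testcat = 0), nGwas = 1e4,
                    seed = 3)
  ss <- simulateSumstats(fx$panel, fx$annot, truth,
                         ldscores = fx$ldscores)
  fit <- fitStratified(ss, fx$ldscores, nBlocks = 20)
  expect_equal(fit@p, pnorm(fit@z, lower.tail = FALSE))
})

test_that("alignment, block-count and collinearity errors are raised", {
  fx <- smallPanelFixture()
  lt <- fx$ldscores
  m <- length(lt@snp)
  ss <- sumStats(lt@snp, chi2 = rep(1, m), n = 1e4)
  expect_error(fitStratified(ss, lt, nBlocks = m + 1), "nBlocks")
  bad <- sumStats(rev(lt@snp), chi2 = rep(1, m), n = 1e4)
  expect_error(fitStratified(bad, lt), "aligned")
  # duplicated category triggers the collinearity error, never silence
  dup <- new("LdScoreTable", snp = lt@snp,
             scores = cbind(ldScores(lt),
                            testcat_copy = ldScores(lt)[, "testcat"]),
             totalLd = totalLd(lt), window = lt@window, adjusted = FALSE)
  expect_error(fitStratified(ss, dup, nBlocks = 20),
               "collinear.*testcat", ignore.case = TRUE)
  # empty category refused
  empt <- new("LdScoreTable", snp = lt@snp,
              scores = cbind(ldScores(lt), void = rep(0, m)),
              totalLd = totalLd(lt), window = lt@window,
              adjusted = FALSE)
  expect_error(fitStratified(ss, empt, nBlocks = 20), "empty")
})

test_that("jackknife SE approaches the replicate SD as blocks grow", {
  panel <- simulateLdPanel(300, nBlocks = 20, blockSize = 50, rho = 0.4,
                           seed = 17)
  v <- variants(panel)
  annot <- annotationMatrix(v, list(all = rep(1L, nrow(v))))
  lt <- computeLdScores(panel, annot)
  reps <- t(sapply(1:40, function(r) {
    truth <- simTruth(c(all = 5e-7), nGwas = 2e4, seed = 300 + r)
    ss <- simulateSumstats(panel, annot, truth, ldscores = lt)
    sapply(c(5, 50), function(nb)
      fitStratified(ss, lt, nBlocks = nb)@se)
  }))
  empSd <- sd(sapply(1:40, function(r) {
    truth <- simTruth(c(all = 5e-7), nGwas = 2e4, seed = 300 + r)
    ss <- simulateSumstats(panel, annot, truth, ldscores = lt)
    fitStratified(ss, lt, nBlocks = 50)@tau
  }))
  # more blocks brings the SE estimate closer to the replicate SD
  err5 <- abs(mean(reps[, 1]) - empSd)
  err50 <- abs(mean(reps[, 2]) - empSd)
  expect_lte(err50, err5 + 0.3 * empSd)
})

test_that("heritability partitioning sums and normalises correctly", {
  v <- toyVariants(10)
  # two disjoint exhaustive categories
  memb <- cbind(left = c(rep(1L, 4), rep(0L, 6)),
                right = c(rep(0L, 4), rep(1L, 6)))
  annot <- annotationMatrix(v, memb)
  fit <- new("LdscFit", categories = c("left", "right"),
             tau = c(2e-6, 1e-6), se = c(1e-7, 1e-7), z = c(20, 10),
             p = c(1e-10, 1e-10), intercept = 1, interceptSe = 0.1,
             nBlocks = 5L, nSnps = 10L, weighting = "ols",
             trait = "sim")
  part <- partitionHeritability(fit, annot)
  expect_equal(sum(part$prop_snps), 1)
  expect_equal(sum(part$prop_h2), 1)
  # single all-SNPs category: enrichment exactly 1
  annotAll <- annotationMatrix(v, cbind(all = rep(1L, 10)))
  fitAll <- new("LdscFit", categories = "all", tau = 1e-6, se = 1e-7,
                z = 10, p = 1e-10, intercept = 1, interceptSe = 0.1,
                nBlocks = 5L, nSnps = 10L, weighting = "ols",
                trait = "sim")
  expect_equal(partitionHeritability(fitAll, annotAll)$enrichment, 1)
  # zero-tau category with members: enrichment 0
  fit0 <- new("LdscFit", categories = c("left", "right"),
              tau = c(0, 1e-6), se = c(1e-7, 1e-7), z = c(0, 10),
              p = c(0.5, 1e-10), intercept = 1, interceptSe = 0.1,
              nBlocks = 5L, nSnps = 10L, weighting = "ols",
              trait = "sim")
  part0 <- partitionHeritability(fit0, annot)
  expect_equal(part0$enrichment[part0$category == "left"], 0)
  # degenerate non-positive total flagged, enrichment missing
  fitNeg <- new("LdscFit", categories = "all", tau = -1e-6, se = 1e-7,
                z = -10, p = 0.999, intercept = 1, interceptSe = 0.1,
                nBlocks = 5L, nSnps = 10L, weighting = "ols",
                trait = "sim")
  expect_warning(pn <- partitionHeritability(fitNeg, annotAll),
                 "non-positive")
  expect_true(is.na(pn$enrichment))
})

test_that("the Bonferroni threshold divides alpha by traits x categories", {
  expect_equal(signif(bonferroniThreshold(0.05, 2, 53), 3), 4.72e-4)
  expect_equal(bonferroniThreshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 2, 30), 0.05 / 60,
               tolerance = 1e-12)
})
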