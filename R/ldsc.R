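## Stratified LD-score regression: per-category LD scores, the
## chi-square-on-LD-score regression with block-jackknife standard
## errors, heritability partitioning, and the Bonferroni threshold over
## traits x categories.

#' Compute per-category LD scores
#'
#' `l(j,C)` is the sum, over SNPs k in category C on the same chromosome
#' with `|pos_k - pos_j| <= window`, of the squared genotype correlation
#' `r2_jk` (including k = j when j is in C). With `adjust = TRUE` each
#' r2 is replaced by the finite-sample-unbiased `r2 - (1 - r2)/(n - 2)`.
#' The table also carries the total LD score l(j) over all panel SNPs,
#' used for regression weighting.
#'
#' Computation is windowed and vectorised: per chromosome, standardized
#' genotype chunks are cross-multiplied against their in-window
#' neighbours, so cost is O(m * window_size) rather than O(m^2).
#'
#' @param panel an [LdPanel-class].
#' @param annot an [AnnotationMatrix-class] sharing the panel's variant
#'   universe.
#' @param window physical window in bp; default 1e6.
#' @param adjust apply the finite-sample r2 correction; needs
#'   `nIndividuals >= 3`.
#' @return An [LdScoreTable-class].
#' @export
computeLdScores <- function(panel, annot, window = 1e6, adjust = FALSE) {
  stopifnot(is(panel, "LdPanel"), is(annot, "AnnotationMatrix"))
  if (window <= 0) stop("'window' must be > 0", call. = FALSE)
  if (!identical(variants(panel)$snp_id, variants(annot)$snp_id))
    stop("panel and annotation variant universes differ", call. = FALSE)
  n <- panel@nIndividuals
  adjust <- .checkFlag(adjust, "adjust")
  if (adjust && n < 3)
    stop("r2 adjustment needs at least 3 individuals", call. = FALSE)

  vt <- variants(panel)
  g <- genotypes(panel)
  memb <- membership(annot)
  m <- nrow(vt)
  scores <- matrix(0, m, ncol(memb), dimnames = list(vt$snp_id,
                                                     colnames(memb)))
  tot <- numeric(m)

  for (chr in unique(vt$chromosome)) {
    idx <- which(vt$chromosome == chr)
    pos <- vt$position[idx]
    # standardize once; columns are already sorted by position
    x <- scale(g[, idx, drop = FALSE])
    denom <- n - 1
    chunk <- 500L
    starts <- seq(1L, length(idx), by = chunk)
    for (s in starts) {
      cols <- s:min(s + chunk - 1L, length(idx))
      lo <- findInterval(pos[cols[1]] - window - 1, pos) + 1L
      hi <- findInterval(pos[cols[length(cols)]] + window, pos)
      nb <- lo:hi
      r <- crossprod(x[, cols, drop = FALSE],
                     x[, nb, drop = FALSE]) / denom
      r2 <- r * r
      if (adjust) r2 <- r2 - (1 - r2) / (n - 2)
      inWin <- abs(outer(pos[cols], pos[nb], "-")) <= window
      r2[!inWin] <- 0
      scores[idx[cols], ] <- scores[idx[cols], , drop = FALSE] +
        r2 %*% memb[idx[nb], , drop = FALSE]
      tot[idx[cols]] <- tot[idx[cols]] + rowSums(r2)
    }
  }
  new("LdScoreTable", snp = vt$snp_id, scores = scores, totalLd = tot,
      window = as.numeric(window), adjusted = adjust)
}

## Internal WLS solve returning coefficients; X includes the intercept.
.wlsCoef <- function(xtx, xty) solve(xtx, xty)

#' Fit the stratified LD-score regression
#'
#' Regresses per-SNP chi-square statistics on `N * l(j,C)` for every
#' category C, with a free intercept. Standard errors come from a
#' delete-one block jackknife over `nBlocks` contiguous SNP blocks, the
#' coefficient z-score is tau/se, and the reported p-value is the
#' one-tailed upper normal tail (testing a *positive* contribution to
#' heritability). With `weighting = "ldsc_weights"` (the default), a
#' first OLS pass supplies fitted values and second-pass weights
#' `1/max(l(j), 1) * 1/(2 * yhat_j^2)` (heteroskedasticity and SNP
#' overcounting; fitted values are floored at 1, the model's lower bound
#' on E[chi2], before inverting); `"ols"` fits unweighted.
#'
#' @param sumstats a [SumStats-class] aligned to `ldscores`.
#' @param ldscores an [LdScoreTable-class]; all categories enter the
#'   model. Empty categories (all-zero LD-score columns) are refused.
#' @param nBlocks jackknife blocks; default 200 (capped only by the
#'   requirement `nBlocks <= n_SNPs`).
#' @param weighting `"ldsc_weights"` or `"ols"`.
#' @return An [LdscFit-class].
#' @export
fitStratified <- function(sumstats, ldscores, nBlocks = 200,
                          weighting = c("ldsc_weights", "ols")) {
  weighting <- match.arg(weighting)
  stopifnot(is(sumstats, "SumStats"), is(ldscores, "LdScoreTable"))
  if (!identical(sumstats@snp, ldscores@snp))
    stop("sumstats and LD scores are not aligned on the same SNPs",
         call. = FALSE)
  y <- chi2(sumstats)
  m <- length(y)
  nBlocks <- .checkCount(nBlocks, "nBlocks")
  if (nBlocks > m)
    stop("nBlocks exceeds the number of SNPs", call. = FALSE)
  L <- ldScores(ldscores)
  empty <- colSums(abs(L)) == 0
  if (any(empty))
    stop("empty annotation categories cannot be regressed on: ",
         paste(colnames(L)[empty], collapse = ", "), call. = FALSE)
  N <- if (length(sampleSize(sumstats)) == 1L)
    rep(sampleSize(sumstats), m) else sampleSize(sumstats)

  X <- cbind(intercept = 1, N * L)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("collinear annotation categories: ",
         paste(setdiff(bad, "intercept"), collapse = ", "), call. = FALSE)
  }

  w <- rep(1, m)
  if (weighting == "ldsc_weights") {
    beta0 <- qr.coef(qrX, y)
    yhat <- pmax(as.vector(X %*% beta0), 1)
    w <- 1 / pmax(totalLd(ldscores), 1) / (2 * yhat^2)
  }

  # per-block weighted cross-products for a fast delete-one jackknife
  blockId <- ceiling(seq_len(m) / (m / nBlocks))
  blockId[blockId > nBlocks] <- nBlocks
  p <- ncol(X)
  xtxB <- array(0, c(p, p, nBlocks))
  xtyB <- matrix(0, p, nBlocks)
  Xw <- X * w
  for (b in seq_len(nBlocks)) {
    rows <- blockId == b
    xtxB[, , b] <- crossprod(X[rows, , drop = FALSE],
                             Xw[rows, , drop = FALSE])
    xtyB[, b] <- crossprod(Xw[rows, , drop = FALSE], y[rows])
  }
  xtx <- rowSums(xtxB, dims = 2)
  xty <- rowSums(xtyB)
  theta <- .wlsCoef(xtx, xty)

  jack <- matrix(0, p, nBlocks)
  for (b in seq_len(nBlocks))
    jack[, b] <- .wlsCoef(xtx - xtxB[, , b], xty - xtyB[, b])
  jbar <- rowMeans(jack)
  se <- sqrt((nBlocks - 1) / nBlocks * rowSums((jack - jbar)^2))

  tau <- theta[-1]
  tauSe <- se[-1]
  z <- tau / tauSe
  # clamp into the open interval: an exact fit (se = 0) would otherwise
  # produce a degenerate p of exactly 0 or 1
  p <- pmin(pmax(stats::pnorm(z, lower.tail = FALSE),
                 .Machine$double.xmin), 1 - .Machine$double.eps)
  new("LdscFit",
      categories = colnames(L), tau = unname(tau), se = unname(tauSe),
      z = unname(z), p = unname(p),
      intercept = unname(theta[1]), interceptSe = unname(se[1]),
      nBlocks = nBlocks, nSnps = as.integer(m), weighting = weighting,
      trait = sumstats@trait)
}

#' Partition heritability across annotation categories
#'
#' `prop_snps(C)` is the fraction of SNPs in C. The heritability assigned
#' to C sums, over its member SNPs, the per-SNP variance implied by every
#' category containing that SNP (`sum_{C' : j in C'} tau_{C'}`);
#' enrichment is `(h2(C)/h2_total) / prop_snps(C)`. A non-positive total
#' is flagged degenerate and enrichment is reported missing.
#'
#' @param fit an [LdscFit-class].
#' @param annot the [AnnotationMatrix-class] the fit was run against.
#' @return data.frame with `category`, `prop_snps`, `prop_h2`,
#'   `enrichment`.
#' @export
partitionHeritability <- function(fit, annot) {
  stopifnot(is(fit, "LdscFit"), is(annot, "AnnotationMatrix"))
  memb <- membership(annot)
  if (!identical(colnames(memb), categories(fit)))
    stop("fit and annotation categories are not aligned", call. = FALSE)
  m <- nrow(memb)
  perSnp <- as.vector(memb %*% fit@tau)
  h2Tot <- sum(perSnp)
  h2C <- as.vector(crossprod(memb, perSnp))
  propSnps <- colSums(memb) / m
  if (h2Tot <= 0) {
    warning("total heritability estimate is non-positive; ",
            "enrichment reported missing", call. = FALSE)
    enr <- rep(NA_real_, ncol(memb))
    propH2 <- rep(NA_real_, ncol(memb))
  } else {
    propH2 <- h2C / h2Tot
    enr <- ifelse(propSnps > 0, propH2 / propSnps, NA_real_)
  }
  data.frame(category = colnames(memb), prop_snps = propSnps,
             prop_h2 = propH2, enrichment = enr, row.names = NULL)
}

#' Bonferroni threshold over traits x annotation categories
#'
#' The study convention divides alpha by the number of GWAS traits times
#' the number of annotation categories tested in the analysis set;
#' e.g. 0.05/(2 x 53) = 4.72e-4.
#'
#' @param alpha significance level.
#' @param nTraits number of GWAS traits.
#' @param nCategories number of annotation categories.
#' @return The threshold `alpha / (nTraits * nCategories)`.
#' @export
#' @examples
#' bonferroniThreshold(0.05, 2, 53)
bonferroniThreshold <- function(alpha, nTraits, nCategories) {
  nTraits <- .checkCount(nTraits, "nTraits")
  nCategories <- .checkCount(nCategories, "nCategories")
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  alpha / (nTraits * nCategories)
}
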