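## Accessors and show methods. Slots are never reached into from user code.

#' @rdname cellHerit-accessors
#' @export
setMethod("genotypes", "LdPanel", function(x) x@genotypes)

#' @rdname cellHerit-accessors
#' @export
setMethod("variants", "LdPanel", function(x) x@variants)

#' @rdname cellHerit-accessors
#' @export
setMethod("variants", "AnnotationMatrix", function(x) x@variants)

#' @rdname cellHerit-accessors
#' @export
setMethod("blockIndex", "LdPanel", function(x) x@blockIndex)

#' @rdname cellHerit-accessors
#' @export
setMethod("membership", "AnnotationMatrix", function(x) x@membership)

#' @rdname cellHerit-accessors
#' @export
setMethod("categories", "AnnotationMatrix",
          function(x) colnames(x@membership))

#' @rdname cellHerit-accessors
#' @export
setMethod("categories", "LdScoreTable", function(x) colnames(x@scores))

#' @rdname cellHerit-accessors
#' @export
setMethod("categories", "LdscFit", function(x) x@categories)

#' @rdname cellHerit-accessors
#' @export
setMethod("ldScores", "LdScoreTable", function(x) x@scores)

#' @rdname cellHerit-accessors
#' @export
setMethod("totalLd", "LdScoreTable", function(x) x@totalLd)

#' @rdname cellHerit-accessors
#' @export
setMethod("chi2", "SumStats", function(x) x@chi2)

#' @rdname cellHerit-accessors
#' @export
setMethod("sampleSize", "SumStats", function(x) x@n)

#' @rdname cellHerit-accessors
#' @export
setMethod("specificity", "SpecificityMatrix", function(x) x@specificity)

#' @rdname cellHerit-accessors
#' @export
setMethod("geneCovariates", "SpecificityMatrix", function(x) x@covariates)

#' @rdname cellHerit-accessors
#' @export
setMethod("geneCovariates", "ExpressionFixture", function(x) x@geneMeta)

#' Per-category coefficient table of a stratified fit
#'
#' @rdname cellHerit-accessors
#' @export
setMethod("coefTable", "LdscFit", function(x) {
  data.frame(category = x@categories, tau = x@tau, se = x@se, z = x@z,
             coefficient_p = x@p, row.names = NULL)
})

#' @rdname cellHerit-accessors
#' @export
setMethod("ewceTable", "EwceResult", function(x) x@results)

## show ----------------------------------------------------------------------

setMethod("show", "LdPanel", function(object) {
  cat("LdPanel:", object@nIndividuals, "individuals x",
      ncol(object@genotypes), "variants in",
      length(unique(object@blockIndex)), "LD blocks\n")
})

setMethod("show", "AnnotationMatrix", function(object) {
  cs <- colSums(object@membership)
  cat("AnnotationMatrix:", nrow(object@membership), "SNPs x",
      ncol(object@membership), "categories\n")
  cat("  members per category:",
      paste(sprintf("%s=%d", colnames(object@membership), cs),
            collapse = ", "), "\n")
})

setMethod("show", "LdScoreTable", function(object) {
  cat("LdScoreTable:", length(object@snp), "SNPs x",
      ncol(object@scores), "categories; window",
      format(object@window, big.mark = ","), "bp",
      if (object@adjusted) "(r2 adjusted)" else "(r2 unadjusted)", "\n")
})

setMethod("show", "SumStats", function(object) {
  cat("SumStats for trait", sQuote(object@trait), ":",
      length(object@snp), "SNPs, mean chi2 =",
      signif(mean(object@chi2), 4), ", N =",
      signif(object@n[1], 4), "\n")
})

setMethod("show", "LdscFit", function(object) {
  cat("LdscFit (", object@weighting, ", ", object@nBlocks,
      " jackknife blocks, ", object@nSnps, " SNPs)\n", sep = "")
  print(coefTable(object), digits = 4)
  cat("intercept:", signif(object@intercept, 4), "( se",
      signif(object@interceptSe, 3), ")\n")
})

setMethod("show", "ExpressionFixture", function(object) {
  cat("ExpressionFixture:", nrow(object@expr), "genes x",
      ncol(object@expr), "groups;",
      length(unlist(object@plantedMarkers)), "planted markers\n")
})

setMethod("show", "SpecificityMatrix", function(object) {
  cat("SpecificityMatrix:", nrow(object@specificity), "genes x",
      ncol(object@specificity), "cell types;",
      length(object@dropped), "zero-expression genes dropped\n")
})

setMethod("show", "EwceResult", function(object) {
  cat("EwceResult:", length(object@targetUsed), "target genes,",
      object@nBoot, "bootstraps, matching =", object@matching, "\n")
  print(object@results, digits = 4)
})
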