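#' @name cellHerit-accessors
#' @title Accessors for cellHerit S4 containers
#' @description Slot accessors: `genotypes()`, `variants()`,
#'   `blockIndex()`, `membership()`, `categories()`, `ldScores()`,
#'   `totalLd()`, `chi2()`, `sampleSize()`, `coefTable()`,
#'   `specificity()`, `geneCovariates()`, `ewceTable()`.
#' @param x an object of the documented class.
#' @return The slot contents (see each method).
NULL

#' @rdname cellHerit-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("blockIndex", function(x) standardGeneric("blockIndex"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("ldScores", function(x) standardGeneric("ldScores"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("totalLd", function(x) standardGeneric("totalLd"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("chi2", function(x) standardGeneric("chi2"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("geneCovariates", function(x) standardGeneric("geneCovariates"))

#' @rdname cellHerit-accessors
#' @export
setGeneric("ewceTable", function(x) standardGeneric("ewceTable"))
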