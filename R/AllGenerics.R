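# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))
#' @rdname accessors
#' @export
setGeneric("testMethod", function(x) standardGeneric("testMethod"))
#' @rdname accessors
#' @export
setGeneric("decorrelated", function(x) standardGeneric("decorrelated"))
#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("snpWeights", function(x) standardGeneric("snpWeights"))
#' @rdname accessors
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))
#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))
#' @rdname accessors
#' @export
setGeneric("noncentralities", function(x) standardGeneric("noncentralities"))
#' @rdname accessors
#' @export
setGeneric("gammaC", function(x) standardGeneric("gammaC"))
#' @rdname accessors
#' @export
setGeneric("powerValue", function(x) standardGeneric("powerValue"))
#' @rdname accessors
#' @export
setGeneric("mcSE", function(x) standardGeneric("mcSE"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("anchorSNP", function(x) standardGeneric("anchorSNP"))
#' @rdname accessors
#' @export
setGeneric("blockLD", function(x) standardGeneric("blockLD"))
#' @rdname accessors
#' @export
setGeneric("geneResults", function(x) standardGeneric("geneResults"))
#' @rdname accessors
#' @export
setGeneric("contributorTable", function(x) standardGeneric("contributorTable"))

#' Accessors for dotgsa objects
#'
#' Small, self-describing accessors for the S4 result and data classes:
#' \code{pValue}, \code{testStatistic}, \code{testMethod} and
#' \code{decorrelated} for \code{\linkS4class{AssocTest}}; \code{zScores},
#' \code{snpIds} and \code{snpWeights} for \code{\linkS4class{StatVector}};
#' \code{transformMatrix} for \code{\linkS4class{DecorTransform}};
#' \code{mixtureWeights}, \code{noncentralities} and \code{gammaC} for
#' \code{\linkS4class{ChiSqMixture}}; \code{powerValue} and \code{mcSE} for
#' \code{\linkS4class{PowerEstimate}}; \code{members}, \code{anchorSNP} and
#' \code{blockLD} for \code{\linkS4class{GeneBlock}}; \code{geneResults} and
#' \code{contributorTable} for \code{\linkS4class{GeneReport}}.
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases pValue testStatistic testMethod decorrelated zScores snpIds
#'   snpWeights transformMatrix mixtureWeights noncentralities gammaC
#'   powerValue mcSE members anchorSNP blockLD geneResults contributorTable
NULL

setMethod("pValue", "AssocTest", function(x) x@pValue)
setMethod("testStatistic", "AssocTest", function(x) x@statistic)
setMethod("testMethod", "AssocTest", function(x) x@method)
setMethod("decorrelated", "AssocTest", function(x) x@decorrelated)
setMethod("zScores", "StatVector", function(x) x@z)
setMethod("snpIds", "StatVector", function(x) x@ids)
setMethod("snpWeights", "StatVector", function(x) x@weights)
setMethod("transformMatrix", "DecorTransform", function(x) x@H)
setMethod("mixtureWeights", "ChiSqMixture", function(x) x@lambda)
setMethod("noncentralities", "ChiSqMixture", function(x) x@gamma)
setMethod("gammaC", "ChiSqMixture", function(x) x@gammaC)
setMethod("powerValue", "PowerEstimate", function(x) x@power)
setMethod("mcSE", "PowerEstimate", function(x) x@mcSE)
setMethod("members", "GeneBlock", function(x) x@members)
setMethod("anchorSNP", "GeneBlock", function(x) x@anchor)
setMethod("blockLD", "GeneBlock", function(x) x@ld)
setMethod("geneResults", "GeneReport", function(x) x@results)
setMethod("contributorTable", "GeneReport", function(x) x@contributors)

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix of %d SNPs", nrow(object)))
  off <- object[row(object) != col(object)]
  if (length(off))
    cat(sprintf("; off-diagonal range [%.3f, %.3f]", min(off), max(off)))
  cat("\n")
  if (!is.null(rownames(object)))
    cat("  labels:", paste(utils::head(rownames(object), 5), collapse = ", "),
        if (nrow(object) > 5) "..." else "", "\n")
})

setMethod("show", "StatVector", function(object) {
  cat(sprintf("StatVector of %d Z-scores (range %.3f to %.3f)%s\n",
              length(object@z), min(object@z), max(object@z),
              if (length(object@weights)) ", weighted" else ""))
})

setMethod("show", "AssocTest", function(object) {
  cat(sprintf("%s test: statistic = %.4g, P = %.4g\n",
              toupper(object@method), object@statistic, object@pValue))
})

setMethod("show", "ChiSqMixture", function(object) {
  cat(sprintf(
    "ChiSqMixture: %d components, total df %g, gammaC = %.4g\n",
    length(object@lambda), sum(object@df), object@gammaC))
})

setMethod("show", "DecorTransform", function(object) {
  cat(sprintf("DecorTransform (symmetric inverse square root), L = %d\n",
              nrow(object@H)))
  cat(sprintf("  eigenvalue range of source R: [%.4g, %.4g]\n",
              min(object@lambda), max(object@lambda)))
})

setMethod("show", "PowerEstimate", function(object) {
  cat(sprintf("%s power at alpha = %g: %.4f (%s%s)\n",
              toupper(object@method), object@alpha, object@power, object@mode,
              if (is.finite(object@mcSE))
                sprintf(", MC SE %.2g", object@mcSE) else ""))
})

setMethod("show", "GeneBlock", function(object) {
  cat(sprintf("GeneBlock: anchor %s, %d SNPs (|r| >= %g)\n",
              object@anchor, length(object@members), object@threshold))
})

setMethod("show", "GeneReport", function(object) {
  cat(sprintf("GeneReport for %s (L = %d)\n", object@gene,
              length(object@block@members)))
  for (r in object@results)
    cat(sprintf("  %-5s P = %.4g\n", toupper(r@method), r@pValue))
  if (nrow(object@contributors))
    cat(sprintf("  top contributors over %d components\n",
                length(unique(object@contributors$component))))
})
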