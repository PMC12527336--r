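#' @describeIn QPBIN virus (row) names.
#' @param x,object a QPBIN.
#' @export
setMethod("virusNames", "QPBIN", function(x) rownames(x@values))

#' @describeIn QPBIN host (column) names.
#' @export
setMethod("hostNames", "QPBIN", function(x) colnames(x@values))

#' @describeIn QPBIN correction log.
#' @export
setMethod("corrections", "QPBIN", function(x) x@corrections)

#' @describeIn QPBIN the underlying infection-strength matrix.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "QPBIN", function(x, ...) x@values)

#' @describeIn QPPIN virus names (rows = columns).
#' @param x,object a QPPIN.
#' @export
setMethod("virusNames", "QPPIN", function(x) rownames(x@values))

#' @describeIn QPPIN correction log.
#' @export
setMethod("corrections", "QPPIN", function(x) x@corrections)

#' @describeIn QPPIN the underlying interaction-factor matrix.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "QPPIN", function(x, ...) x@values)

#' @describeIn QPBIN compact description of the network.
#' @export
setMethod("show", "QPBIN", function(object) {
  v <- object@values
  pos <- sum(v > 0)
  cat(sprintf("QPBIN: %d viruses x %d hosts, %d infections (fill %.3f)\n",
              nrow(v), ncol(v), pos,
              if (length(v)) pos / length(v) else 0))
  if (nrow(object@corrections))
    cat(sprintf("  %d input corrections applied\n", nrow(object@corrections)))
})

#' @describeIn QPPIN compact description of the interaction matrix.
#' @export
setMethod("show", "QPPIN", function(object) {
  w <- object@values
  off <- w[row(w) != col(w)]
  cat(sprintf("QPPIN: %d viruses, %d antagonistic and %d synergistic pairs (directed)\n",
              nrow(w), sum(off < 1), sum(off > 1)))
})

#' Is an interaction matrix all-neutral?
#'
#' @param qppin a [QPPIN-class].
#' @return TRUE when every factor equals 1, i.e. the matrix carries no
#'   antagonism or synergy information.
#' @export
isNeutral <- function(qppin) all(as.matrix(qppin) == 1)

#' @describeIn CocktailEvaluation one-line summary of the evaluation.
#' @param object a CocktailEvaluation.
#' @export
setMethod("show", "CocktailEvaluation", function(object) {
  cat(sprintf(
    "Cocktail {%s}: coverage %d, total inhibition %.4f, antagonism burden %.4f, mean redundancy %.2f\n",
    paste(object@viruses, collapse = ", "), object@coverage,
    object@totalInhibition, object@antagonismBurden, object@meanRedundancy))
})

#' @describeIn DesignResult summary of winners per size.
#' @param object a DesignResult.
#' @export
setMethod("show", "DesignResult", function(object) {
  cat(sprintf("DesignResult (%s, %s): %d subsets examined\n",
              object@config@algorithm, object@config@objective,
              object@subsetsExamined))
  if (length(object@overallBest)) {
    ev <- object@overallBest$evaluation
    cat("  overall best: ")
    show(ev)
  } else cat("  no feasible cocktail found\n")
  if (length(object@uncoverableHosts))
    cat("  uncoverable hosts:", paste(object@uncoverableHosts, collapse = ", "), "\n")
})

#' @describeIn NetworkSummary print the headline statistics.
#' @param object a NetworkSummary.
#' @export
setMethod("show", "NetworkSummary", function(object) {
  cat(sprintf("NetworkSummary (tau = %g): fill %.4f, entropy %.4f bits, density %.4f\n",
              object@tau, object@fill, object@entropyBits, object@density))
  cat(sprintf("  %d viruses, %d hosts\n",
              nrow(object@perPhage), nrow(object@perHost)))
})
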