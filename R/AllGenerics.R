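#' Virus identifiers of a network object
#' @param x a QPBIN or QPPIN.
#' @return character vector of virus names.
#' @export
setGeneric("virusNames", function(x) standardGeneric("virusNames"))

#' Host identifiers of a QPBIN
#' @param x a QPBIN.
#' @return character vector of host names.
#' @export
setGeneric("hostNames", function(x) standardGeneric("hostNames"))

#' Correction log of a parsed matrix
#'
#' Every silent repair applied while reading an input matrix (clamped
#' out-of-range cells, non-numeric cells set to 0, neutral fill-in of
#' missing viruses, forced diagonal) is recorded with its location, the
#' original token, the corrected value and the rule applied.
#'
#' @param x a QPBIN or QPPIN.
#' @return data.frame with columns location, original, corrected, rule.
#' @export
setGeneric("corrections", function(x) standardGeneric("corrections"))
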