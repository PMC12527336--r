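#' @import methods
NULL

.emptyCorrections <- function() {
  data.frame(location = character(), original = character(),
             corrected = character(), rule = character(),
             stringsAsFactors = FALSE)
}

#' QPBIN: quantitative phage-bacteria infection network
#'
#' A virus-by-host matrix of infection strengths on a 0 (no lysis) to
#' 1 (complete lysis) scale. Rows are viruses (phages), columns are
#' bacterial hosts; row and column names are the unique identifiers used
#' throughout the package. A correction log records every silent repair
#' applied while parsing the source file (clamping, non-numeric cells).
#'
#' @slot values numeric matrix in \[0, 1\] with unique rownames (viruses)
#'   and colnames (hosts).
#' @slot corrections data.frame with columns \code{location},
#'   \code{original}, \code{corrected}, \code{rule}; one row per repaired
#'   cell.
#'
#' @seealso [readQPBIN()], [QPBIN()] the constructor, [QPPIN-class]
#' @aliases QPBIN-class
#' @exportClass QPBIN
setClass("QPBIN",
  slots = c(values = "matrix", corrections = "data.frame"))

setValidity("QPBIN", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if ((nrow(v) > 0 && is.null(rownames(v))) ||
      (ncol(v) > 0 && is.null(colnames(v))))
    msg <- c(msg, "values must have virus rownames and host colnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate virus names")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate host names")
  }
  if (is.numeric(v) && length(v) &&
      (anyNA(v) || min(v) < 0 || max(v) > 1))
    msg <- c(msg, "infection strengths must lie in [0, 1] with no NA")
  if (length(msg)) msg else TRUE
})

#' QPPIN: quantitative phage-phage interaction network
#'
#' A square virus-by-virus matrix of multiplicative interaction factors.
#' Entry \code{w[p, q]} is the factor applied to the virulence of phage
#' \code{p} when phage \code{q} is co-formulated: 1 is neutral (or
#' unknown), values below 1 are antagonistic with 0 meaning complete
#' lethality of the interference, and values above 1 are synergistic.
#' The matrix is read as directed; symmetric inputs behave symmetrically.
#'
#' @slot values non-negative numeric square matrix, diagonal 1, with
#'   identical unique row and column virus names.
#' @slot corrections data.frame correction log (see [QPBIN-class]).
#'
#' @seealso [readQPPIN()], [neutralQPPIN()], [QPBIN-class]
#' @aliases QPPIN-class
#' @exportClass QPPIN
setClass("QPPIN",
  slots = c(values = "matrix", corrections = "data.frame"))

setValidity("QPPIN", function(object) {
  w <- object@values
  msg <- character()
  if (!is.numeric(w)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(w) != ncol(w)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
    msg <- c(msg, "row and column virus names must be identical")
  else if (anyDuplicated(rownames(w)))
    msg <- c(msg, "duplicate virus names")
  if (is.numeric(w) && length(w)) {
    if (anyNA(w) || min(w) < 0)
      msg <- c(msg, "interaction factors must be non-negative and non-NA")
    if (nrow(w) == ncol(w) && any(diag(w) != 1))
      msg <- c(msg, "diagonal must be 1 (a phage is neutral to itself)")
  }
  if (length(msg)) msg else TRUE
})

#' Descriptive summary of a QPBIN
#'
#' Holds the network-level statistics used to characterise an infection
#' network: matrix fill, its binary entropy in bits, edge density
#' (edges per node over the bipartite node set), per-phage host range
#' and virulence, and per-host counts of lysing phages. All edge counts
#' use the infection threshold \code{tau}: a cell is an edge when its
#' value exceeds \code{tau}.
#'
#' @slot fill fraction of cells above \code{tau}.
#' @slot entropyBits binary entropy of the fill, in bits.
#' @slot density edges divided by (number of viruses + number of hosts).
#' @slot perPhage data.frame: virus, hostRange (fraction of hosts),
#'   meanVirulence (over all hosts), meanVirulenceInfected (over infected
#'   hosts only).
#' @slot perHost data.frame: host, lysingPhages (the resistance profile
#'   d(h): how many phages lyse the host).
#' @slot tau infection threshold used.
#' @aliases NetworkSummary-class
#' @seealso [summarizeNetwork()]
#' @exportClass NetworkSummary
setClass("NetworkSummary",
  slots = c(fill = "numeric", entropyBits = "numeric", density = "numeric",
            perPhage = "data.frame", perHost = "data.frame", tau = "numeric"))

#' Evaluation of a phage cocktail on a network
#'
#' Quality metrics of one cocktail (virus subset) under the co-infection
#' model: per-host predicted growth inhibition, host coverage, total
#' inhibition, co-infection redundancy, pairwise antagonism burden, and
#' the marginal contribution of each member virus.
#'
#' @slot viruses character vector, the cocktail members.
#' @slot perHostInhibition named numeric, predicted inhibition I(h|C) in
#'   \[0, 1\] per host.
#' @slot coverage integer, number of hosts with inhibition above the
#'   threshold.
#' @slot totalInhibition sum of per-host inhibitions.
#' @slot meanRedundancy mean number of effectively lysing cocktail phages
#'   over covered hosts (0 when nothing is covered).
#' @slot antagonismBurden sum over ordered virus pairs in the cocktail of
#'   max(0, 1 - w(p, q)).
#' @slot redundancyExcess sum over hosts of max(0, count - target) under
#'   the redundancy target used at evaluation time.
#' @slot perVirusContribution named numeric, drop in total inhibition when
#'   the virus is removed from the cocktail.
#' @slot tau infection threshold used.
#' @aliases CocktailEvaluation-class
#' @seealso [evaluateCocktail()], [compareCocktails()]
#' @exportClass CocktailEvaluation
setClass("CocktailEvaluation",
  slots = c(viruses = "character", perHostInhibition = "numeric",
            coverage = "integer", totalInhibition = "numeric",
            meanRedundancy = "numeric", antagonismBurden = "numeric",
            redundancyExcess = "numeric", perVirusContribution = "numeric",
            tau = "numeric"))

#' Configuration of a cocktail design run
#'
#' @slot maxSize hard cap on cocktail size (default 12); smaller winning
#'   cocktails are preferred by the size tie-break.
#' @slot algorithm "exhaustive" or "network_metrics" (greedy heuristic).
#' @slot objective "coverage_first" (broad host range, minimal antagonism)
#'   or "virulence_first" (maximal total predicted inhibition).
#' @slot tau infection threshold; any value above it counts as infection.
#' @slot redundancyMode "ignore", "minimize_excess" (penalise co-infection
#'   beyond the target as a late tie-break) or "require_min" (demand at
#'   least the target number of lysing phages on every coverable host).
#' @slot redundancyTarget the redundancy target r* (default 2).
#' @slot nCocktails number of phage-disjoint cocktails for rotation design.
#' @slot enumerationBudget maximum number of subsets the exhaustive search
#'   may examine.
#' @slot seed integer seed for synthetic inputs (NA when unused).
#' @aliases DesignConfig-class
#' @seealso [designConfig()]
#' @exportClass DesignConfig
setClass("DesignConfig",
  slots = c(maxSize = "integer", algorithm = "character",
            objective = "character", tau = "numeric",
            redundancyMode = "character", redundancyTarget = "integer",
            nCocktails = "integer", enumerationBudget = "numeric",
            seed = "integer"))

setValidity("DesignConfig", function(object) {
  msg <- character()
  if (object@maxSize < 1L) msg <- c(msg, "maxSize must be >= 1")
  if (!object@algorithm %in% c("exhaustive", "network_metrics"))
    msg <- c(msg, "algorithm must be 'exhaustive' or 'network_metrics'")
  if (!object@objective %in% c("coverage_first", "virulence_first"))
    msg <- c(msg, "objective must be 'coverage_first' or 'virulence_first'")
  if (object@tau < 0 || object@tau >= 1)
    msg <- c(msg, "tau must lie in [0, 1)")
  if (!object@redundancyMode %in% c("ignore", "minimize_excess", "require_min"))
    msg <- c(msg, "unknown redundancyMode")
  if (object@redundancyTarget < 1L) msg <- c(msg, "redundancyTarget must be >= 1")
  if (object@nCocktails < 1L) msg <- c(msg, "nCocktails must be >= 1")
  if (object@enumerationBudget <= 0) msg <- c(msg, "enumerationBudget must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of one cocktail design run
#'
#' @slot bestPerSize named list, one entry per cocktail size that produced
#'   a feasible candidate; each entry is a list with elements
#'   \code{cocktail} (character) and \code{evaluation}
#'   ([CocktailEvaluation-class]).
#' @slot overallBest list(cocktail, evaluation) for the best cocktail over
#'   all sizes under the configured objective; empty list when the network
#'   admits no cocktail.
#' @slot uncoverableHosts hosts no phage lyses; excluded from coverage.
#' @slot removedViruses phages with empty host range, pruned before search.
#' @slot subsetsExamined number of candidate subsets evaluated.
#' @slot config the [DesignConfig-class] used.
#' @aliases DesignResult-class
#' @seealso [exhaustiveSearch()], [greedySearch()]
#' @exportClass DesignResult
setClass("DesignResult",
  slots = c(bestPerSize = "list", overallBest = "list",
            uncoverableHosts = "character", removedViruses = "character",
            subsetsExamined = "numeric", config = "DesignConfig"))

#' Structured cocktail design report
#'
#' A pure function of the inputs and the configuration: echoes the
#' configuration, lists input corrections, summarises the network, and
#' tabulates the best cocktails per size under both objective orderings,
#' with a per-virus/per-host breakdown of the winners. When several
#' rotation cocktails were requested the series section lists them.
#'
#' @slot config the [DesignConfig-class] echoed.
#' @slot corrections combined correction log of both input matrices.
#' @slot networkSummary a [NetworkSummary-class].
#' @slot resultCoverage [DesignResult-class] under coverage_first ordering.
#' @slot resultVirulence [DesignResult-class] under virulence_first ordering.
#' @slot series list of [DesignResult-class], the rotation series (length 1
#'   when a single cocktail was requested).
#' @slot breakdowns named list of data.frames (virus, host, expected lysis
#'   efficiency) for the selected and, when present, the
#'   antagonism-minimised alternative winner.
#' @slot seriesWarnings character, warnings emitted by the series design.
#' @slot qppinNeutral TRUE when the interaction matrix is all-neutral (the
#'   antagonism-minimised alternative section is then omitted).
#' @aliases DesignReport-class
#' @seealso [buildReport()], [renderReport()]
#' @exportClass DesignReport
setClass("DesignReport",
  slots = c(config = "DesignConfig", corrections = "data.frame",
            networkSummary = "NetworkSummary",
            resultCoverage = "DesignResult", resultVirulence = "DesignResult",
            series = "list", breakdowns = "list", seriesWarnings = "character",
            qppinNeutral = "logical"))

#' Construct a QPBIN from a numeric matrix
#'
#' @param values numeric matrix of infection strengths in \[0, 1\].
#' @param virusNames,hostNames optional dimension names; taken from
#'   \code{dimnames(values)} when omitted.
#' @param corrections optional correction log data.frame.
#' @return a validated [QPBIN-class] object.
#' @examples
#' m <- matrix(c(0.9, 0, 0, 0.5), 2, 2)
#' QPBIN(m, virusNames = c("V1", "V2"), hostNames = c("H1", "H2"))
#' @export
QPBIN <- function(values, virusNames = rownames(values),
                  hostNames = colnames(values),
                  corrections = .emptyCorrections()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(virusNames, hostNames)
  new("QPBIN", values = values, corrections = corrections)
}

#' Construct a QPPIN from a numeric matrix
#'
#' @param values non-negative square numeric matrix with unit diagonal.
#' @param virusNames optional virus names (row and column).
#' @param corrections optional correction log data.frame.
#' @return a validated [QPPIN-class] object.
#' @examples
#' neutralQPPIN(c("V1", "V2"))
#' @export
QPPIN <- function(values, virusNames = rownames(values),
                  corrections = .emptyCorrections()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(virusNames, virusNames)
  new("QPPIN", values = values, corrections = corrections)
}

#' All-neutral QPPIN for a set of viruses
#'
#' Every pairwise factor is 1 ("neutral or unknown"); this is the default
#' interaction matrix when no QPPIN file is supplied.
#'
#' @param virusNames character vector of virus identifiers.
#' @return a [QPPIN-class] with all entries 1.
#' @export
neutralQPPIN <- function(virusNames) {
  n <- length(virusNames)
  QPPIN(matrix(1, n, n), virusNames = virusNames)
}

#' Design run configuration
#'
#' @param maxSize maximum cocktail size (default 12).
#' @param algorithm "exhaustive" (optimal, enumerates all subsets) or
#'   "network_metrics" (greedy heuristic for large networks).
#' @param objective "coverage_first" ranks by host coverage, then minimal
#'   antagonism, then total inhibition; "virulence_first" ranks by total
#'   predicted inhibition first.
#' @param tau infection threshold in \[0, 1); default 0 (any positive
#'   infection strength counts).
#' @param redundancyMode co-infection redundancy policy: "ignore",
#'   "minimize_excess" (default; excess over the target breaks late ties)
#'   or "require_min" (filter to cocktails with at least the target
#'   number of lysing phages per coverable host).
#' @param redundancyTarget redundancy target r* (default 2, the
#'   at-least-two-phages-per-host proposal).
#' @param nCocktails number of phage-disjoint rotation cocktails.
#' @param enumerationBudget maximum subsets the exhaustive search may
#'   visit before aborting (default 5e6).
#' @param seed integer seed for synthetic input generation; NA when unused.
#' @return a [DesignConfig-class].
#' @examples
#' designConfig(maxSize = 3, algorithm = "exhaustive")
#' @export
designConfig <- function(maxSize = 12L, algorithm = "exhaustive",
                         objective = "coverage_first", tau = 0,
                         redundancyMode = "minimize_excess",
                         redundancyTarget = 2L, nCocktails = 1L,
                         enumerationBudget = 5e6, seed = NA_integer_) {
  new("DesignConfig", maxSize = as.integer(maxSize), algorithm = algorithm,
      objective = objective, tau = as.numeric(tau),
      redundancyMode = redundancyMode,
      redundancyTarget = as.integer(redundancyTarget),
      nCocktails = as.integer(nCocktails),
      enumerationBudget = as.numeric(enumerationBudget),
      seed = as.integer(seed))
}
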