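# Cocktail designers: exhaustive enumeration (optimal under the
# configured ordering) and the network-metrics greedy heuristic
# (resistance-weighted marginal gain), plus phage-disjoint rotation
# series.

#' Prune a network before cocktail search
#'
#' Removes viruses that infect no host (they can never contribute) and
#' flags hosts no virus infects (they can never be covered and are
#' excluded from coverage counts and denominators).
#'
#' @param qpbin a [QPBIN-class].
#' @param tau infection threshold (default 0).
#' @return list with elements \code{qpbin} (reduced network),
#'   \code{removedViruses} and \code{uncoverableHosts}.
#' @export
pruneNetwork <- function(qpbin, tau = 0) {
  v <- as.matrix(qpbin)
  edges <- v > tau
  keepV <- rowSums(edges) > 0
  keepH <- colSums(edges) > 0
  list(qpbin = QPBIN(v[keepV, keepH, drop = FALSE],
                     corrections = corrections(qpbin)),
       removedViruses = rownames(v)[!keepV],
       uncoverableHosts = colnames(v)[!keepH])
}

.alignQPPIN <- function(qpbin, qppin) {
  if (is.null(qppin)) return(neutralQPPIN(virusNames(qpbin)))
  w <- as.matrix(qppin)
  miss <- setdiff(virusNames(qpbin), rownames(w))
  if (length(miss))
    stop("QPPIN is missing viruses: ", paste(miss, collapse = ", "))
  QPPIN(w[virusNames(qpbin), virusNames(qpbin), drop = FALSE])
}

.emptyResult <- function(config, prune, examined = 0) {
  new("DesignResult", bestPerSize = list(), overallBest = list(),
      uncoverableHosts = prune$uncoverableHosts,
      removedViruses = prune$removedViruses,
      subsetsExamined = examined, config = config)
}

.feasible <- function(ev, config, dvec) {
  if (config@redundancyMode != "require_min") return(TRUE)
  r <- config@redundancyTarget
  covered <- ev$inhibition > config@tau
  relevant <- covered & dvec >= r
  all(ev$counts[relevant] >= r)
}

# Promote a winning .evalCore list into the (cocktail, evaluation) pair
# stored in a DesignResult, recomputing the full S4 evaluation with
# per-virus contributions.
.promote <- function(ev, qpbin, qppin, config) {
  list(cocktail = ev$viruses,
       evaluation = evaluateCocktail(ev$viruses, qpbin, qppin,
                                     tau = config@tau,
                                     redundancyTarget = config@redundancyTarget))
}

.finishResult <- function(bestBySize, examined, qpbin, qppin, config, prune) {
  if (!length(bestBySize)) return(.emptyResult(config, prune, examined))
  overall <- bestBySize[[1L]]
  for (e in bestBySize[-1L])
    if (.betterEval(e, overall, config@objective, config@redundancyMode))
      overall <- e
  bps <- lapply(bestBySize, .promote, qpbin = qpbin, qppin = qppin,
                config = config)
  names(bps) <- vapply(bestBySize, function(e) as.character(e$size), "")
  new("DesignResult", bestPerSize = bps,
      overallBest = .promote(overall, qpbin, qppin, config),
      uncoverableHosts = prune$uncoverableHosts,
      removedViruses = prune$removedViruses,
      subsetsExamined = examined, config = config)
}

#' Exhaustive cocktail search
#'
#' Enumerates every virus subset of size 1 up to the configured cap and
#' keeps, for each size, the best cocktail under [compareCocktails()]
#' with the configured objective; the overall best is the winner across
#' sizes. Deterministic and optimal under the ordering; intended for
#' smaller networks — the run aborts if the number of subsets would
#' exceed the enumeration budget.
#'
#' @param qpbin a [QPBIN-class].
#' @param qppin a [QPPIN-class] or NULL (all-neutral).
#' @param config a [DesignConfig-class].
#' @return a [DesignResult-class].
#' @examples
#' fx <- workedExampleFixture()
#' res <- exhaustiveSearch(fx$qpbin, fx$qppin, designConfig(maxSize = 3))
#' res@overallBest$cocktail
#' @export
exhaustiveSearch <- function(qpbin, qppin = NULL, config = designConfig()) {
  qppin <- .alignQPPIN(qpbin, qppin)
  prune <- pruneNetwork(qpbin, config@tau)
  q <- prune$qpbin
  n <- length(virusNames(q))
  if (n == 0L) return(.emptyResult(config, prune))
  qp <- QPPIN(as.matrix(qppin)[virusNames(q), virusNames(q), drop = FALSE])
  vmat <- as.matrix(q)
  wmat <- as.matrix(qp)
  kmax <- min(config@maxSize, n)
  nSubsets <- sum(choose(n, seq_len(kmax)))
  if (nSubsets > config@enumerationBudget)
    stop(sprintf(paste0(
      "exhaustive search would examine %.0f subsets (budget %.0f); ",
      "use algorithm = 'network_metrics' or a smaller maxSize"),
      nSubsets, config@enumerationBudget))
  dvec <- colSums(vmat > config@tau)
  examined <- 0
  bestBySize <- list()
  for (k in seq_len(kmax)) {
    best <- NULL
    combos <- utils::combn(n, k)
    for (j in seq_len(ncol(combos))) {
      examined <- examined + 1
      ev <- .evalCore(vmat, wmat, combos[, j], config@tau,
                      config@redundancyTarget)
      if (!.feasible(ev, config, dvec)) next
      if (is.null(best) ||
          .betterEval(ev, best, config@objective, config@redundancyMode))
        best <- ev
    }
    if (!is.null(best)) bestBySize[[length(bestBySize) + 1L]] <- best
  }
  .finishResult(bestBySize, examined, q, qp, config, prune)
}

#' Greedy network-metrics cocktail search
#'
#' Computationally cheap heuristic for exploratory analyses and large
#' networks. Phages are added one at a time; at each step the phage with
#' the largest resistance-weighted marginal gain
#' \deqn{\sum_h \frac{1}{d(h)} [I(h|S \cup \{p\}) - I(h|S)]}
#' is selected, where d(h) is the number of phages lysing host h in the
#' pruned network — hosts killed by few phages dominate the choice.
#' Selection stops at the size cap or when no phage yields a positive
#' gain; ties fall to the lexicographically smaller virus name. The best
#' cocktail per size is the greedy prefix of that size.
#'
#' @inheritParams exhaustiveSearch
#' @return a [DesignResult-class].
#' @examples
#' fx <- workedExampleFixture()
#' res <- greedySearch(fx$qpbin, fx$qppin, designConfig(maxSize = 3))
#' res@overallBest$cocktail
#' @export
greedySearch <- function(qpbin, qppin = NULL, config = designConfig()) {
  qppin <- .alignQPPIN(qpbin, qppin)
  prune <- pruneNetwork(qpbin, config@tau)
  q <- prune$qpbin
  n <- length(virusNames(q))
  if (n == 0L) return(.emptyResult(config, prune))
  qp <- QPPIN(as.matrix(qppin)[virusNames(q), virusNames(q), drop = FALSE])
  vmat <- as.matrix(q)
  wmat <- as.matrix(qp)
  dvec <- colSums(vmat > config@tau)
  weight <- 1 / dvec  # pruned network: dvec >= 1 everywhere
  sel <- integer()
  examined <- 0
  prefixes <- list()
  current <- .evalCore(vmat, wmat, sel, config@tau, config@redundancyTarget)
  kmax <- min(config@maxSize, n)
  while (length(sel) < kmax) {
    candidates <- setdiff(seq_len(n), sel)
    bestGain <- 0
    bestIdx <- NA_integer_
    bestEv <- NULL
    for (p in candidates[order(rownames(vmat)[candidates])]) {
      examined <- examined + 1
      ev <- .evalCore(vmat, wmat, c(sel, p), config@tau,
                      config@redundancyTarget)
      gain <- sum(weight * (ev$inhibition - current$inhibition))
      if (gain > bestGain + 1e-12) {
        bestGain <- gain
        bestIdx <- p
        bestEv <- ev
      }
    }
    if (is.na(bestIdx)) break
    sel <- c(sel, bestIdx)
    current <- bestEv
    prefixes[[length(prefixes) + 1L]] <- bestEv
  }
  feasible <- Filter(function(e) .feasible(e, config, dvec), prefixes)
  .finishResult(feasible, examined, q, qp, config, prune)
}

#' Run the configured search algorithm
#'
#' Dispatches to [exhaustiveSearch()] or [greedySearch()] according to
#' \code{config@algorithm}.
#'
#' @inheritParams exhaustiveSearch
#' @return a [DesignResult-class].
#' @export
designCocktail <- function(qpbin, qppin = NULL, config = designConfig()) {
  switch(config@algorithm,
         exhaustive = exhaustiveSearch(qpbin, qppin, config),
         network_metrics = greedySearch(qpbin, qppin, config))
}

#' Design a series of phage-disjoint rotation cocktails
#'
#' For long-term treatment, several cocktails applied in rotation delay
#' the evolution of bacterial resistance. Cocktails are designed
#' sequentially; each subsequent design excludes every virus already
#' used, so the series is strictly phage-disjoint. The series stops early
#' (with a warning) when the remaining viruses cover nothing.
#'
#' @inheritParams exhaustiveSearch
#' @return list of [DesignResult-class], at most \code{config@nCocktails}
#'   long.
#' @examples
#' fx <- workedExampleFixture()
#' series <- designCocktailSeries(fx$qpbin, fx$qppin,
#'                                designConfig(maxSize = 3, nCocktails = 2))
#' lapply(series, function(r) r@overallBest$cocktail)
#' @export
designCocktailSeries <- function(qpbin, qppin = NULL, config = designConfig()) {
  qppin <- .alignQPPIN(qpbin, qppin)
  remaining <- virusNames(qpbin)
  out <- list()
  for (i in seq_len(config@nCocktails)) {
    if (!length(remaining)) {
      warning(sprintf("viruses exhausted: only %d of %d cocktails designed",
                      length(out), config@nCocktails))
      break
    }
    sub <- QPBIN(as.matrix(qpbin)[remaining, , drop = FALSE])
    subw <- QPPIN(as.matrix(qppin)[remaining, remaining, drop = FALSE])
    res <- designCocktail(sub, subw, config)
    if (!length(res@overallBest) ||
        res@overallBest$evaluation@coverage == 0L) {
      warning(sprintf(
        "remaining viruses cover no host: only %d of %d cocktails designed",
        length(out), config@nCocktails))
      break
    }
    out[[i]] <- res
    remaining <- setdiff(remaining, res@overallBest$cocktail)
  }
  out
}
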