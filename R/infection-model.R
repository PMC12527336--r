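# Quantitative co-infection model.
#
# Within a cocktail C the raw virulence v(p, h) of phage p is modulated
# multiplicatively by the interaction factors of its co-formulated
# partners and clamped to [0, 1]:
#     v_eff(p, h | C) = min(1, v(p, h) * prod_{q in C, q != p} w(p, q))
# Phages then act independently on each host (noisy-OR):
#     I(h | C) = 1 - prod_{p in C} (1 - v_eff(p, h | C))

# Fast path used by the search loops: plain matrices, integer row index,
# no S4 construction, no per-virus contributions.
.evalCore <- function(vmat, wmat, idx, tau, rTarget) {
  k <- length(idx)
  if (k == 0L) {
    nh <- ncol(vmat)
    return(list(viruses = character(), inhibition = numeric(nh),
                coverage = 0L, total = 0, burden = 0, meanRedundancy = 0,
                excess = 0, counts = integer(nh), size = 0L,
                key = ""))
  }
  wsub <- wmat[idx, idx, drop = FALSE]
  # diagonal is 1, so the row product over the whole sub-matrix is the
  # product over partners q != p
  factors <- apply(wsub, 1L, prod)
  veff <- vmat[idx, , drop = FALSE] * factors
  veff[veff > 1] <- 1
  inhib <- 1 - apply(1 - veff, 2L, prod)
  covered <- inhib > tau
  counts <- as.integer(colSums(veff > tau))
  burden <- sum(pmax(0, 1 - wsub)) # diag contributes 0
  nms <- rownames(vmat)[idx]
  list(viruses = nms,
       inhibition = inhib,
       coverage = sum(covered),
       total = sum(inhib),
       burden = burden,
       meanRedundancy = if (any(covered)) mean(counts[covered]) else 0,
       excess = sum(pmax(0L, counts - rTarget)),
       counts = counts,
       size = k,
       key = paste(sort(nms), collapse = ","))
}

.resolveViruses <- function(vmat, viruses) {
  idx <- match(viruses, rownames(vmat))
  if (anyNA(idx))
    stop("unknown viruses: ", paste(viruses[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx)) stop("cocktail contains duplicate viruses")
  idx
}

#' Effective virulence of a phage within a cocktail
#'
#' The raw infection strength v(p, h) multiplied by the interaction
#' factors w(p, q) of every co-formulated partner q, clamped to \[0, 1\].
#' With an all-neutral QPPIN this is exactly v(p, h); a partner with
#' w(p, q) = 0 (complete lethality) silences the phage entirely.
#'
#' @param p virus name (must be a member of \code{cocktail}).
#' @param h host name.
#' @param cocktail character vector of cocktail members.
#' @param qpbin a [QPBIN-class].
#' @param qppin a [QPPIN-class] (NULL = all-neutral).
#' @return effective virulence in \[0, 1\].
#' @examples
#' fx <- workedExampleFixture()
#' effectiveVirulence("phage1", "b1", c("phage1", "phage3"),
#'                    fx$qpbin, fx$qppin)
#' @export
effectiveVirulence <- function(p, h, cocktail, qpbin, qppin = NULL) {
  vmat <- as.matrix(qpbin)
  if (is.null(qppin)) qppin <- neutralQPPIN(virusNames(qpbin))
  wmat <- as.matrix(qppin)
  idx <- .resolveViruses(vmat, cocktail)
  if (!p %in% cocktail) stop("virus '", p, "' is not in the cocktail")
  if (!h %in% colnames(vmat)) stop("unknown host: ", h)
  wsub <- wmat[match(cocktail, rownames(wmat)),
               match(cocktail, rownames(wmat)), drop = FALSE]
  fac <- prod(wsub[match(p, cocktail), ])
  min(1, max(0, vmat[p, h] * fac))
}

#' Predicted growth inhibition of a host under a cocktail
#'
#' Independent action (noisy-OR) across the cocktail's phages:
#' I(h|C) = 1 - prod(1 - v_eff(p, h | C)). The empty cocktail yields 0;
#' a single phage with effective virulence 1 yields complete lysis.
#'
#' @param h host name.
#' @inheritParams effectiveVirulence
#' @return inhibition in \[0, 1\].
#' @examples
#' fx <- workedExampleFixture()
#' hostInhibition("b3", c("phage1", "phage4", "phage5"), fx$qpbin, fx$qppin)
#' @export
hostInhibition <- function(h, cocktail, qpbin, qppin = NULL) {
  vmat <- as.matrix(qpbin)
  if (is.null(qppin)) qppin <- neutralQPPIN(virusNames(qpbin))
  if (!h %in% colnames(vmat)) stop("unknown host: ", h)
  idx <- .resolveViruses(vmat, cocktail)
  ev <- .evalCore(vmat, as.matrix(qppin), idx, tau = 0, rTarget = 1L)
  unname(ev$inhibition[match(h, colnames(vmat))])
}

#' Evaluate a cocktail on a network
#'
#' Computes every quality metric of a cocktail: per-host predicted
#' inhibition, coverage (hosts with inhibition above \code{tau}), total
#' inhibition, mean co-infection redundancy over covered hosts,
#' antagonism burden (sum over ordered in-cocktail pairs of
#' max(0, 1 - w(p, q))), and each virus's marginal contribution — the
#' drop in total inhibition if it were removed.
#'
#' @param cocktail character vector of viruses (may be empty).
#' @param qpbin a [QPBIN-class].
#' @param qppin a [QPPIN-class] or NULL for all-neutral.
#' @param tau infection threshold (default 0).
#' @param redundancyTarget target used for the redundancy-excess metric
#'   (default 2).
#' @return a [CocktailEvaluation-class].
#' @examples
#' fx <- workedExampleFixture()
#' evaluateCocktail(c("phage1", "phage4", "phage5"), fx$qpbin, fx$qppin)
#' @export
evaluateCocktail <- function(cocktail, qpbin, qppin = NULL, tau = 0,
                             redundancyTarget = 2L) {
  vmat <- as.matrix(qpbin)
  if (is.null(qppin)) qppin <- neutralQPPIN(virusNames(qpbin))
  wmat <- as.matrix(qppin)
  if (!identical(rownames(wmat), rownames(vmat)))
    stop("QPPIN viruses do not match the QPBIN")
  idx <- .resolveViruses(vmat, cocktail)
  ev <- .evalCore(vmat, wmat, idx, tau, redundancyTarget)
  contrib <- numeric(length(idx))
  names(contrib) <- cocktail
  for (j in seq_along(idx)) {
    sub <- .evalCore(vmat, wmat, idx[-j], tau, redundancyTarget)
    contrib[j] <- ev$total - sub$total
  }
  inhib <- ev$inhibition
  names(inhib) <- colnames(vmat)
  new("CocktailEvaluation", viruses = cocktail, perHostInhibition = inhib,
      coverage = as.integer(ev$coverage), totalInhibition = ev$total,
      meanRedundancy = ev$meanRedundancy, antagonismBurden = ev$burden,
      redundancyExcess = ev$excess, perVirusContribution = contrib,
      tau = tau)
}

# Ranking of evaluations (internal, operates on .evalCore lists).
# Returns TRUE when a is strictly better than b.
.keyVector <- function(e, objective, redundancyMode) {
  base <- switch(objective,
    coverage_first  = c(-e$coverage, e$burden, -e$total, e$size),
    virulence_first = c(-e$total, -e$coverage, e$burden, e$size),
    stop("unknown objective: ", objective))
  if (redundancyMode == "minimize_excess") base <- c(base, e$excess)
  base
}

.betterEval <- function(a, b, objective, redundancyMode) {
  ka <- .keyVector(a, objective, redundancyMode)
  kb <- .keyVector(b, objective, redundancyMode)
  for (i in seq_along(ka)) {
    if (ka[i] < kb[i]) return(TRUE)
    if (ka[i] > kb[i]) return(FALSE)
  }
  # deterministic final tie-break: lexicographically smaller virus list
  a$key < b$key
}

.asEvalList <- function(e) {
  list(viruses = e@viruses, inhibition = unname(e@perHostInhibition),
       coverage = e@coverage, total = e@totalInhibition,
       burden = e@antagonismBurden, meanRedundancy = e@meanRedundancy,
       excess = e@redundancyExcess, size = length(e@viruses),
       key = paste(sort(e@viruses), collapse = ","))
}

#' Compare two cocktail evaluations under a design objective
#'
#' Total deterministic order used by both search algorithms.
#' \code{"coverage_first"} (broad host range / minimal antagonism) ranks
#' by coverage (descending), antagonism burden (ascending), total
#' inhibition (descending), then size (ascending);
#' \code{"virulence_first"} ranks by total inhibition, coverage, burden,
#' size. Under \code{redundancyMode = "minimize_excess"} the co-infection
#' excess over the redundancy target breaks remaining ties (ascending);
#' the final tie-break is the lexicographically smaller sorted virus list.
#'
#' @param a,b [CocktailEvaluation-class] objects on the same network.
#' @param objective "coverage_first" or "virulence_first".
#' @param redundancyMode "ignore", "minimize_excess" or "require_min".
#' @return -1 if \code{a} ranks above \code{b}, 1 if below, 0 if they are
#'   the same cocktail.
#' @examples
#' fx <- workedExampleFixture()
#' a <- evaluateCocktail(c("phage1", "phage4", "phage5"), fx$qpbin, fx$qppin)
#' b <- evaluateCocktail(c("phage1", "phage3"), fx$qpbin, fx$qppin)
#' compareCocktails(a, b)  # -1: {1,4,5} ranks above {1,3}
#' @export
compareCocktails <- function(a, b, objective = "coverage_first",
                             redundancyMode = "minimize_excess") {
  la <- .asEvalList(a)
  lb <- .asEvalList(b)
  if (identical(la$key, lb$key)) return(0L)
  if (.betterEval(la, lb, objective, redundancyMode)) -1L else 1L
}
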