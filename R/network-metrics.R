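#' Binary entropy of a matrix fill
#'
#' H(f) = -f log2 f - (1 - f) log2(1 - f), the entropy in bits of a
#' Bernoulli(f) cell. It quantifies the combinatorial complexity of an
#' infection matrix: both nearly empty and nearly saturated matrices
#' (H close to 0) admit few distinct cocktails, while half-filled
#' matrices (H = 1 bit) admit the most.
#'
#' @param fill fraction of occupied cells, in \[0, 1\] (vectorised).
#' @return entropy in bits, in \[0, 1\]; H(0) = H(1) = 0 by convention.
#' @examples
#' binaryEntropy(0.5)  # 1 bit
#' binaryEntropy(0.1)
#' @export
binaryEntropy <- function(fill) {
  if (any(!is.finite(fill)) || any(fill < 0) || any(fill > 1))
    stop("fill must lie in [0, 1]")
  term <- function(f) ifelse(f == 0, 0, -f * log2(f))
  term(fill) + term(1 - fill)
}

#' Summarise an infection network
#'
#' Computes the descriptive statistics used to characterise a QPBIN:
#' matrix fill and its binary entropy, edge density (edges per node over
#' viruses + hosts), per-phage host range and mean virulence (over all
#' hosts and over infected hosts only), and each host's resistance
#' profile d(h) — the number of phages that lyse it. A cell is an edge
#' when its value exceeds the threshold \code{tau}.
#'
#' @param qpbin a [QPBIN-class].
#' @param tau infection threshold in \[0, 1) (default 0).
#' @return a [NetworkSummary-class].
#' @examples
#' fx <- workedExampleFixture()
#' summarizeNetwork(fx$qpbin)
#' @export
summarizeNetwork <- function(qpbin, tau = 0) {
  stopifnot(tau >= 0, tau < 1)
  v <- as.matrix(qpbin)
  edges <- v > tau
  nE <- sum(edges)
  fill <- if (length(v)) nE / length(v) else 0
  perPhage <- data.frame(
    virus = rownames(v),
    hostRange = rowSums(edges) / ncol(v),
    meanVirulence = rowMeans(v),
    meanVirulenceInfected = vapply(seq_len(nrow(v)), function(i) {
      inf <- edges[i, ]
      if (any(inf)) mean(v[i, inf]) else 0
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  perHost <- data.frame(host = colnames(v), lysingPhages = colSums(edges),
                        stringsAsFactors = FALSE, row.names = NULL)
  new("NetworkSummary", fill = fill, entropyBits = binaryEntropy(fill),
      density = nE / (nrow(v) + ncol(v)), perPhage = perPhage,
      perHost = perHost, tau = tau)
}

#' Co-infection redundancy profile of a virus subset
#'
#' For each host, how many viruses of the given subset lyse it (value
#' above \code{tau}). On the full virus set this is the host resistance
#' profile d(h); on a cocktail it is the co-infection multiplicity.
#'
#' @param qpbin a [QPBIN-class].
#' @param viruses character vector, subset of the QPBIN viruses.
#' @param tau infection threshold (default 0).
#' @return named integer vector over hosts.
#' @examples
#' fx <- workedExampleFixture()
#' redundancyProfile(fx$qpbin, c("phage1", "phage4", "phage5"))
#' @export
redundancyProfile <- function(qpbin, viruses, tau = 0) {
  v <- as.matrix(qpbin)
  bad <- setdiff(viruses, rownames(v))
  if (length(bad)) stop("unknown viruses: ", paste(bad, collapse = ", "))
  counts <- colSums(v[viruses, , drop = FALSE] > tau)
  storage.mode(counts) <- "integer"
  counts
}

#' Write a network summary as TSV tables
#'
#' @param summary a [NetworkSummary-class].
#' @param file path prefix; writes \code{<file>.phages.tsv},
#'   \code{<file>.hosts.tsv} and \code{<file>.network.tsv}.
#' @return invisibly, the paths written.
#' @export
writeSummaryTSV <- function(summary, file) {
  paths <- paste0(file, c(".network.tsv", ".phages.tsv", ".hosts.tsv"))
  net <- data.frame(fill = summary@fill, entropyBits = summary@entropyBits,
                    density = summary@density, tau = summary@tau)
  utils::write.table(net, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary@perPhage, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary@perHost, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
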