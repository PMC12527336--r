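# Seeded synthetic network generators. All randomness goes through R's
# default Mersenne-Twister RNG inside a local seed scope, so the same
# seed reproduces the same matrices on any platform.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate a random quantitative infection network
#'
#' Each cell is occupied independently with probability
#' \code{targetFill}; occupied cells draw an infection strength uniformly
#' from (0, 1\]. By default matrices with all-zero virus rows or host
#' columns are resampled (such rows/columns carry no information and are
#' pruned before search anyway); set \code{allowEmpty = TRUE} to keep
#' them, e.g. to exercise [pruneNetwork()].
#'
#' @param nViruses,nHosts matrix dimensions.
#' @param targetFill expected fraction of occupied cells in \[0, 1\].
#' @param seed integer seed; the same seed yields the same matrix.
#' @param allowEmpty keep all-zero rows/columns (default FALSE).
#' @return a [QPBIN-class] with viruses \code{virus01...} and hosts
#'   \code{host01...}.
#' @examples
#' randomQPBIN(5, 4, targetFill = 0.4, seed = 1)
#' @export
randomQPBIN <- function(nViruses, nHosts, targetFill = 0.3, seed = 1L,
                        allowEmpty = FALSE) {
  stopifnot(nViruses >= 1, nHosts >= 1, targetFill >= 0, targetFill <= 1)
  .withSeed(seed, {
    draw <- function() {
      occ <- matrix(stats::runif(nViruses * nHosts) < targetFill,
                    nViruses, nHosts)
      vals <- matrix(0, nViruses, nHosts)
      # uniform on (0, 1]: flip runif's [0, 1) half-open side
      vals[occ] <- 1 - stats::runif(sum(occ))
      vals
    }
    vals <- draw()
    if (!allowEmpty && targetFill > 0) {
      tries <- 0L
      while ((any(rowSums(vals) == 0) || any(colSums(vals) == 0)) &&
             tries < 1000L) {
        vals <- draw()
        tries <- tries + 1L
      }
    }
    QPBIN(vals,
          virusNames = sprintf("virus%02d", seq_len(nViruses)),
          hostNames = sprintf("host%02d", seq_len(nHosts)))
  })
}

#' Generate a random phage-phage interaction network
#'
#' Each unordered off-diagonal virus pair is, independently, antagonistic
#' with probability \code{pAntagonism} (both directions drawn uniformly
#' from \code{antagonismRange}), synergistic with probability
#' \code{pSynergy} (factors from \code{synergyRange}), and neutral
#' otherwise. The diagonal is 1.
#'
#' @param virusNames character vector of virus identifiers.
#' @param pAntagonism,pSynergy pair-type probabilities;
#'   \code{pAntagonism + pSynergy <= 1}.
#' @param antagonismRange length-2 numeric in (0, 1): antagonistic factor
#'   bounds.
#' @param synergyRange length-2 numeric in (1, 2\]: synergistic factor
#'   bounds.
#' @param seed integer seed.
#' @return a [QPPIN-class].
#' @examples
#' randomQPPIN(c("a", "b", "c"), pAntagonism = 0.5, seed = 7)
#' @export
randomQPPIN <- function(virusNames, pAntagonism = 0.1, pSynergy = 0.05,
                        antagonismRange = c(0.1, 0.9),
                        synergyRange = c(1.1, 2), seed = 1L) {
  stopifnot(pAntagonism >= 0, pSynergy >= 0, pAntagonism + pSynergy <= 1,
            antagonismRange[1] > 0, antagonismRange[2] < 1,
            synergyRange[1] > 1, synergyRange[2] <= 2)
  n <- length(virusNames)
  .withSeed(seed, {
    w <- matrix(1, n, n, dimnames = list(virusNames, virusNames))
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          u <- stats::runif(1)
          if (u < pAntagonism) {
            w[i, j] <- stats::runif(1, antagonismRange[1], antagonismRange[2])
            w[j, i] <- stats::runif(1, antagonismRange[1], antagonismRange[2])
          } else if (u < pAntagonism + pSynergy) {
            w[i, j] <- stats::runif(1, synergyRange[1], synergyRange[2])
            w[j, i] <- stats::runif(1, synergyRange[1], synergyRange[2])
          }
        }
      }
    }
    QPPIN(w)
  })
}

#' The eight-phage / five-host worked example
#'
#' A small hand-checkable network illustrating why quantitative
#' information matters for cocktail design. Phages 1 and 2 share a binary
#' host range (hosts b1, b2) but phage 1 is more virulent; phages 6, 7
#' and 8 are identical narrow-range phages on b2; phage 3 alone covers
#' hosts b3-b5 but is antagonised by (and antagonises) every other phage
#' with a factor of 0.2; phages 4 and 5 cover b3/b4 and b5 at high
#' virulence with no interference. Purely binary host-range reasoning
#' picks the minimum cover \{phage3, phage1-or-2\}; the quantitative model
#' instead selects \{phage1, phage4, phage5\}, which avoids the
#' antagonism and maximises predicted inhibition. Both outcomes are
#' verified by brute force in the package's test suite.
#'
#' @return list with elements \code{qpbin} ([QPBIN-class], 8 viruses x
#'   5 hosts) and \code{qppin} ([QPPIN-class]).
#' @examples
#' fx <- workedExampleFixture()
#' as.matrix(fx$qpbin)
#' @export
workedExampleFixture <- function() {
  hosts <- paste0("b", 1:5)
  phages <- paste0("phage", 1:8)
  v <- rbind(
    c(0.9, 0.8, 0,   0,   0),
    c(0.6, 0.5, 0,   0,   0),
    c(0,   0,   0.5, 0.5, 0.5),
    c(0,   0,   0.9, 0.9, 0),
    c(0,   0,   0,   0,   0.9),
    c(0,   0.4, 0,   0,   0),
    c(0,   0.4, 0,   0,   0),
    c(0,   0.4, 0,   0,   0))
  qpbin <- QPBIN(v, virusNames = phages, hostNames = hosts)
  w <- matrix(1, 8, 8, dimnames = list(phages, phages))
  w[3, -3] <- 0.2
  w[-3, 3] <- 0.2
  list(qpbin = qpbin, qppin = QPPIN(w))
}
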