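fx <- workedExampleFixture()

test_that("effective virulence applies partner factors multiplicatively", {
  # neutral partners leave the raw value untouched
  expect_equal(effectiveVirulence("phage1", "b1", c("phage1", "phage4"),
                                  fx$qpbin, fx$qppin), 0.9)
  expect_equal(effectiveVirulence("phage1", "b1", c("phage1", "phage2"),
                                  fx$qpbin, NULL), 0.9)
  # antagonised by phage3: 0.9 * 0.2
  expect_equal(effectiveVirulence("phage1", "b1", c("phage1", "phage3"),
                                  fx$qpbin, fx$qppin), 0.18)
  # a complete-lethality partner silences the phage entirely
  q <- QPBIN(matrix(c(0.9, 0.4), 2, 1, dimnames = list(c("a", "b"), "h")))
  w <- QPPIN(matrix(c(1, 1, 0, 1), 2, 2,
                    dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(effectiveVirulence("a", "h", c("a", "b"), q, w), 0)
  # synergy is clamped at 1
  w2 <- QPPIN(matrix(c(1, 1, 1.5, 1), 2, 2,
                     dimnames = list(c("a", "b"), c("a", "b"))))
  q2 <- QPBIN(matrix(c(0.8, 0.4), 2, 1, dimnames = list(c("a", "b"), "h")))
  expect_equal(effectiveVirulence("a", "h", c("a", "b"), q2, w2), 1)
  expect_error(effectiveVirulence("phage5", "b1", c("phage1", "phage2"),
                                  fx$qpbin, fx$qppin), "not in the cocktail")
})

test_that("host inhibition is independent action across phages", {
  q <- QPBIN(matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("a", "b"), "h")))
  expect_equal(hostInhibition("h", c("a", "b"), q), 0.75)
  expect_equal(hostInhibition("h", character(), q), 0)
  q1 <- QPBIN(matrix(1, 1, 1, dimnames = list("a", "h")))
  expect_equal(hostInhibition("h", "a", q1), 1)
})

test_that("cocktail evaluation reproduces the fixture arithmetic", {
  ev <- evaluateCocktail(c("phage1", "phage4", "phage5"), fx$qpbin, fx$qppin)
  expect_equal(ev@coverage, 5L)
  expect_equal(ev@totalInhibition, 4.4)
  expect_equal(ev@antagonismBurden, 0)
  expect_equal(unname(ev@perHostInhibition),
               c(0.9, 0.8, 0.9, 0.9, 0.9))
  expect_equal(ev@meanRedundancy, 1)

  ev13 <- evaluateCocktail(c("phage1", "phage3"), fx$qpbin, fx$qppin)
  expect_equal(ev13@coverage, 5L)
  expect_equal(ev13@totalInhibition, 0.18 + 0.16 + 0.10 + 0.10 + 0.10)
  expect_equal(ev13@antagonismBurden, 2 * (1 - 0.2))

  empty <- evaluateCocktail(character(), fx$qpbin, fx$qppin)
  expect_equal(empty@coverage, 0L)
  expect_equal(empty@totalInhibition, 0)
  expect_length(empty@perVirusContribution, 0)

  expect_error(evaluateCocktail("phageX", fx$qpbin, fx$qppin), "unknown")
})

test_that("per-virus contributions are removal marginals", {
  ev <- evaluateCocktail(c("phage1", "phage4", "phage5"), fx$qpbin, fx$qppin)
  # removing phage1 loses b1 (0.9) and b2 (0.8)
  expect_equal(unname(ev@perVirusContribution["phage1"]), 1.7)
  expect_equal(unname(ev@perVirusContribution["phage4"]), 1.8)
  expect_equal(unname(ev@perVirusContribution["phage5"]), 0.9)
  # a phage silenced by a lethal partner (and neutral toward it)
  # contributes exactly zero
  q <- QPBIN(matrix(c(0.9, 0.4), 2, 1, dimnames = list(c("a", "b"), "h")))
  w <- QPPIN(matrix(c(1, 1, 0, 1), 2, 2,
                    dimnames = list(c("a", "b"), c("a", "b"))))
  evs <- evaluateCocktail(c("a", "b"), q, w)
  expect_equal(unname(evs@perVirusContribution["a"]), 0)
})

test_that("antagonism can make a cocktail worse", {
  base <- evaluateCocktail(c("phage1", "phage4", "phage5"), fx$qpbin, fx$qppin)
  with3 <- evaluateCocktail(c("phage1", "phage3", "phage4", "phage5"),
                            fx$qpbin, fx$qppin)
  expect_lt(with3@totalInhibition, base@totalInhibition)
})

test_that("all model outputs stay in [0, 1] for arbitrary non-negative factors", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    viruses <- virusNames(inst$qpbin)
    set.seed(seed + 500)
    # stress with synergy well above the generator's usual range
    w <- as.matrix(inst$qppin)
    boost <- sample(length(w), 3)
    w[boost] <- runif(3, 1, 5)
    diag(w) <- 1
    qppin <- QPPIN(w)
    for (rep in 1:5) {
      k <- sample(seq_along(viruses), 1)
      cocktail <- sort(sample(viruses, k))
      ev <- evaluateCocktail(cocktail, inst$qpbin, qppin)
      expect_true(all(ev@perHostInhibition >= 0 & ev@perHostInhibition <= 1))
      for (p in cocktail) {
        ve <- effectiveVirulence(p, hostNames(inst$qpbin)[1], cocktail,
                                 inst$qpbin, qppin)
        expect_gte(ve, 0)
        expect_lte(ve, 1)
      }
    }
  }
})

test_that("with a neutral QPPIN the model reduces to the raw matrix", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    viruses <- virusNames(inst$qpbin)
    hosts <- hostNames(inst$qpbin)
    v <- as.matrix(inst$qpbin)
    set.seed(seed)
    cocktail <- sort(sample(viruses, min(4, length(viruses))))
    for (p in cocktail[1:2]) {
      h <- sample(hosts, 1)
      expect_equal(effectiveVirulence(p, h, cocktail, inst$qpbin, NULL),
                   unname(v[p, h]))
    }
    # inhibition (hence coverage) grows monotonically under set inclusion
    prev <- evaluateCocktail(character(), inst$qpbin, NULL)
    for (k in seq_along(cocktail)) {
      cur <- evaluateCocktail(cocktail[seq_len(k)], inst$qpbin, NULL)
      expect_true(all(cur@perHostInhibition >= prev@perHostInhibition - 1e-12))
      expect_gte(cur@coverage, prev@coverage)
      expect_true(all(cur@perVirusContribution >= -1e-12))
      prev <- cur
    }
  }
})

test_that("binary matrices with neutral interactions reduce to set cover", {
  set.seed(42)
  for (rep in 1:10) {
    v <- matrix(rbinom(30, 1, 0.4), 5, 6,
                dimnames = list(paste0("p", 1:5), paste0("h", 1:6)))
    q <- QPBIN(v)
    cocktail <- sort(sample(rownames(v), 3))
    ev <- evaluateCocktail(cocktail, q, NULL)
    expect_equal(ev@coverage,
                 sum(colSums(v[cocktail, , drop = FALSE]) > 0))
  }
})

test_that("cocktail comparison follows the objective orderings", {
  a <- evaluateCocktail(c("phage1", "phage4", "phage5"), fx$qpbin, fx$qppin)
  b <- evaluateCocktail(c("phage1", "phage3"), fx$qpbin, fx$qppin)
  # equal coverage; a wins on antagonism burden (coverage_first) and on
  # total inhibition (virulence_first)
  expect_equal(compareCocktails(a, b, "coverage_first"), -1L)
  expect_equal(compareCocktails(a, b, "virulence_first"), -1L)
  # same host range, higher virulence: phage1 ranks above phage2
  e1 <- evaluateCocktail("phage1", fx$qpbin, fx$qppin)
  e2 <- evaluateCocktail("phage2", fx$qpbin, fx$qppin)
  expect_equal(compareCocktails(e1, e2, "coverage_first"), -1L)
  expect_equal(compareCocktails(e1, e2, "virulence_first"), -1L)
  # identical metrics: lexicographically smaller virus list wins
  e6 <- evaluateCocktail("phage6", fx$qpbin, fx$qppin)
  e7 <- evaluateCocktail("phage7", fx$qpbin, fx$qppin)
  expect_equal(compareCocktails(e6, e7), -1L)
  expect_equal(compareCocktails(e7, e6), 1L)
  expect_equal(compareCocktails(e6, e6), 0L)
})
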