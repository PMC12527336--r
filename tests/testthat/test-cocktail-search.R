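fx <- workedExampleFixture()

test_that("pruning removes empty viruses and flags uncoverable hosts", {
  v <- as.matrix(fx$qpbin)
  withZeros <- QPBIN(cbind(rbind(v, phage9 = 0), b6 = 0))
  pr <- pruneNetwork(withZeros)
  expect_identical(pr$removedViruses, "phage9")
  expect_identical(pr$uncoverableHosts, "b6")
  expect_equal(dim(as.matrix(pr$qpbin)), c(8L, 5L))
  # the fixture itself is already irreducible
  clean <- pruneNetwork(fx$qpbin)
  expect_length(clean$removedViruses, 0)
  expect_length(clean$uncoverableHosts, 0)
  expect_equal(as.matrix(clean$qpbin), v)
})

test_that("exhaustive search solves the worked example", {
  res <- exhaustiveSearch(fx$qpbin, fx$qppin, designConfig(maxSize = 3))
  expect_setequal(res@overallBest$cocktail, c("phage1", "phage4", "phage5"))
  expect_equal(res@overallBest$evaluation@coverage, 5L)
  expect_equal(res@overallBest$evaluation@totalInhibition, 4.4)
  expect_equal(res@subsetsExamined, choose(8, 1) + choose(8, 2) + choose(8, 3))
  # binary host-range-only view picks the minimum cover {phage3, phage1}
  bin <- binarizeQPBIN(fx$qpbin)
  resBin <- exhaustiveSearch(bin, NULL, designConfig(maxSize = 3))
  expect_setequal(resBin@overallBest$cocktail, c("phage1", "phage3"))
})

test_that("K = 1 returns the best singleton and best-per-size is populated", {
  res <- exhaustiveSearch(fx$qpbin, fx$qppin, designConfig(maxSize = 1))
  expect_identical(names(res@bestPerSize), "1")
  expect_identical(res@overallBest$cocktail, res@bestPerSize[["1"]]$cocktail)
  # singleton maximising coverage (3 hosts) is phage3
  expect_identical(res@overallBest$cocktail, "phage3")
  resV <- exhaustiveSearch(fx$qpbin, fx$qppin,
                           designConfig(maxSize = 1,
                                        objective = "virulence_first"))
  expect_identical(resV@overallBest$cocktail, "phage4")  # 1.8 total
})

test_that("the enumeration budget guards against blow-up", {
  expect_error(
    exhaustiveSearch(fx$qpbin, fx$qppin,
                     designConfig(maxSize = 8, enumerationBudget = 10)),
    "network_metrics")
})

test_that("exhaustive search matches the brute-force oracle on random instances", {
  objectives <- c("coverage_first", "virulence_first")
  modes <- c("minimize_excess", "ignore")
  for (seed in 1:30) {
    inst <- random_instance(seed)
    K <- min(4L, length(virusNames(inst$qpbin)))
    obj <- objectives[seed %% 2L + 1L]
    mode <- modes[seed %% 2L + 1L]
    cfg <- designConfig(maxSize = K, objective = obj, redundancyMode = mode)
    res <- exhaustiveSearch(inst$qpbin, inst$qppin, cfg)
    orc <- oracle_best(as.matrix(inst$qpbin), as.matrix(inst$qppin), K,
                       objective = obj, mode = mode)
    expect_setequal(res@overallBest$cocktail, orc$best$subset)
  }
})

test_that("greedy coverage never beats exhaustive coverage at any size", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    K <- min(4L, length(virusNames(inst$qpbin)))
    cfg <- designConfig(maxSize = K)
    ex <- exhaustiveSearch(inst$qpbin, inst$qppin, cfg)
    gr <- greedySearch(inst$qpbin, inst$qppin, cfg)
    for (sz in names(gr@bestPerSize)) {
      if (!sz %in% names(ex@bestPerSize)) next
      expect_lte(gr@bestPerSize[[sz]]$evaluation@coverage,
                 ex@bestPerSize[[sz]]$evaluation@coverage)
    }
  }
})

test_that("greedy equals exhaustive on modular (disjoint host-block) instances", {
  q <- modular_instance()
  cfg <- designConfig(maxSize = 4)
  ex <- exhaustiveSearch(q, NULL, cfg)
  gr <- greedySearch(q, NULL, cfg)
  expect_setequal(gr@overallBest$cocktail, ex@overallBest$cocktail)
  for (sz in names(ex@bestPerSize)) {
    expect_setequal(gr@bestPerSize[[sz]]$cocktail,
                    ex@bestPerSize[[sz]]$cocktail)
    expect_equal(gr@bestPerSize[[sz]]$evaluation@coverage,
                 ex@bestPerSize[[sz]]$evaluation@coverage)
  }
})

test_that("greedy finds a full-coverage cocktail on the worked example", {
  res <- greedySearch(fx$qpbin, fx$qppin, designConfig(maxSize = 3))
  expect_equal(res@overallBest$evaluation@coverage, 5L)
  # the resistance-weighted gain avoids the antagonised phage3
  expect_setequal(res@overallBest$cocktail, c("phage1", "phage4", "phage5"))
})

test_that("greedy returns an empty design on an all-zero network", {
  zero <- QPBIN(matrix(0, 3, 3, dimnames = list(paste0("p", 1:3),
                                                paste0("h", 1:3))))
  res <- greedySearch(zero, NULL, designConfig(maxSize = 3))
  expect_length(res@overallBest, 0)
  expect_length(res@bestPerSize, 0)
  expect_identical(sort(res@removedViruses), paste0("p", 1:3))
  expect_identical(sort(res@uncoverableHosts), paste0("h", 1:3))
})

test_that("exhaustive best coverage is non-decreasing in size under neutral QPPIN", {
  for (seed in c(3, 9, 17)) {
    inst <- random_instance(seed)
    res <- exhaustiveSearch(inst$qpbin, NULL, designConfig(maxSize = 4))
    covs <- vapply(res@bestPerSize, function(e) e$evaluation@coverage, 1L)
    expect_true(all(diff(covs) >= 0))
  }
})

test_that("both algorithms are deterministic", {
  for (alg in c("exhaustive", "network_metrics")) {
    cfg <- designConfig(maxSize = 3, algorithm = alg)
    a <- designCocktail(fx$qpbin, fx$qppin, cfg)
    b <- designCocktail(fx$qpbin, fx$qppin, cfg)
    expect_identical(a@overallBest$cocktail, b@overallBest$cocktail)
    expect_identical(a@subsetsExamined, b@subsetsExamined)
    expect_equal(a@overallBest$evaluation@perHostInhibition,
                 b@overallBest$evaluation@perHostInhibition)
  }
})

test_that("require_min filters to cocktails meeting the redundancy floor", {
  # two hosts, each lysed by two phages: r* = 2 forces all four phages
  v <- matrix(c(0.5, 0.6, 0, 0,
                0, 0, 0.7, 0.8), 4, 2,
              dimnames = list(paste0("p", 1:4), c("h1", "h2")))
  q <- QPBIN(v)
  cfg <- designConfig(maxSize = 4, redundancyMode = "require_min",
                      redundancyTarget = 2)
  res <- exhaustiveSearch(q, NULL, cfg)
  for (entry in res@bestPerSize) {
    counts <- redundancyProfile(q, entry$cocktail)
    covered <- entry$evaluation@perHostInhibition > 0
    expect_true(all(counts[covered] >= 2))
  }
  expect_setequal(res@overallBest$cocktail, paste0("p", 1:4))
})

test_that("rotation series are phage-disjoint and warn on exhaustion", {
  cfg <- designConfig(maxSize = 3, nCocktails = 2)
  series <- designCocktailSeries(fx$qpbin, fx$qppin, cfg)
  expect_length(series, 2)
  c1 <- series[[1]]@overallBest$cocktail
  c2 <- series[[2]]@overallBest$cocktail
  expect_length(intersect(c1, c2), 0)
  expect_setequal(c1, c("phage1", "phage4", "phage5"))

  # n = 1 degenerates to a single search
  single <- designCocktailSeries(fx$qpbin, fx$qppin,
                                 designConfig(maxSize = 3, nCocktails = 1))
  expect_length(single, 1)
  expect_identical(single[[1]]@overallBest$cocktail,
                   exhaustiveSearch(fx$qpbin, fx$qppin,
                                    designConfig(maxSize = 3))@overallBest$cocktail)

  # more cocktails than the virus pool supports
  expect_warning(
    long <- designCocktailSeries(fx$qpbin, fx$qppin,
                                 designConfig(maxSize = 4, nCocktails = 6)),
    "cocktails")
  expect_lt(length(long), 6)
  used <- unlist(lapply(long, function(r) r@overallBest$cocktail))
  expect_false(anyDuplicated(used) > 0)
})
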