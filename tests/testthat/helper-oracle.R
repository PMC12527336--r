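# Independent brute-force oracle for the cocktail search. Written with
# plain nested loops straight from the model definition; deliberately
# shares no code with the package's evaluator or comparator.

oracle_eval <- function(v, w, subset, tau = 0, rstar = 2L) {
  hosts <- colnames(v)
  inhib <- setNames(numeric(length(hosts)), hosts)
  counts <- setNames(integer(length(hosts)), hosts)
  for (h in hosts) {
    survive <- 1
    for (p in subset) {
      fac <- 1
      for (q in subset) if (q != p) fac <- fac * w[p, q]
      ve <- v[p, h] * fac
      if (ve > 1) ve <- 1
      survive <- survive * (1 - ve)
      if (ve > tau) counts[h] <- counts[h] + 1L
    }
    inhib[h] <- 1 - survive
  }
  burden <- 0
  if (length(subset) >= 2) {
    for (i in seq_along(subset)) {
      for (j in seq_along(subset)) {
        if (i != j && w[subset[i], subset[j]] < 1)
          burden <- burden + (1 - w[subset[i], subset[j]])
      }
    }
  }
  covered <- inhib > tau
  list(subset = subset,
       inhib = inhib,
       coverage = sum(covered),
       total = sum(inhib),
       burden = burden,
       excess = sum(pmax(0L, counts - rstar)),
       counts = counts)
}

# TRUE when a beats b under the stated ordering.
oracle_better <- function(a, b, objective, mode) {
  ka <- if (objective == "coverage_first") {
    c(a$coverage, -a$burden, a$total, -length(a$subset))
  } else {
    c(a$total, a$coverage, -a$burden, -length(a$subset))
  }
  kb <- if (objective == "coverage_first") {
    c(b$coverage, -b$burden, b$total, -length(b$subset))
  } else {
    c(b$total, b$coverage, -b$burden, -length(b$subset))
  }
  if (mode == "minimize_excess") {
    ka <- c(ka, -a$excess)
    kb <- c(kb, -b$excess)
  }
  for (i in seq_along(ka)) {
    if (ka[i] > kb[i]) return(TRUE)
    if (ka[i] < kb[i]) return(FALSE)
  }
  paste(sort(a$subset), collapse = ",") < paste(sort(b$subset), collapse = ",")
}

# Naive re-enumeration with a running maximum. Returns the best subset
# (character vector) over sizes 1..K, plus best coverage per size.
oracle_best <- function(v, w, K, objective = "coverage_first",
                        mode = "minimize_excess", tau = 0, rstar = 2L) {
  viruses <- rownames(v)
  best <- NULL
  coverage_by_size <- integer(0)
  for (k in seq_len(min(K, length(viruses)))) {
    combos <- combn(viruses, k, simplify = FALSE)
    best_cov <- 0L
    for (s in combos) {
      e <- oracle_eval(v, w, s, tau, rstar)
      if (e$coverage > best_cov) best_cov <- e$coverage
      if (is.null(best) || oracle_better(e, best, objective, mode))
        best <- e
    }
    coverage_by_size[k] <- best_cov
  }
  list(best = best, coverage_by_size = coverage_by_size)
}
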