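---
title: "Designing phage cocktails from quantitative interaction networks"
author: "PhageMix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing phage cocktails from quantitative interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhageMix)
```

## The problem

A phage cocktail is a set of bacteriophages co-administered against a
panel of bacterial hosts. Classical design treats the host-range matrix
as binary and solves a set-cover problem, but binary matrices cannot
distinguish a weakly lysing phage from a strongly lysing one, and they
ignore phage–phage interference entirely — both effects are documented
causes of cocktails underperforming their best single member. PhageMix
works from two quantitative inputs:

* a **QPBIN**, a virus × host matrix `v(p, h) ∈ [0, 1]` of infection
  strengths (0 = no lysis, 1 = complete lysis). Raw assay scores on
  other scales (e.g. 0–3 cross-streak virulence) can be divided down on
  import with `readQPBIN(..., rescale = 3)`;
* a **QPPIN**, a square virus × virus matrix `w(p, q) ≥ 0` of
  multiplicative interaction factors: 1 neutral or unknown, below 1
  antagonistic (0 = complete lethality of the interference), above 1
  synergistic. The matrix is read as *directed* — `w(p, q)` is the
  effect **on** `p` **of** `q` — because nothing forces interference to
  be symmetric; symmetric files simply behave symmetrically.

When no QPPIN is available the package substitutes an all-neutral
matrix, which is exactly the "unknown interaction" semantics of the
factor 1.

## The co-infection model

Two composition rules turn the matrices into a prediction for a cocktail
`C`:

1. **Within a phage**: partners act multiplicatively on its virulence,
   `v_eff(p, h | C) = min(1, v(p, h) · Π_{q ∈ C, q ≠ p} w(p, q))`.
   The product is the simplest composition consistent with
   "multiplicative factor" semantics for pairwise values; alternatives
   (minimum, mean) would not reduce to the pairwise definition when only
   one partner is present. Synergy is applied before clamping, so no
   amount of synergy produces an effective virulence above 1.
2. **Across phages**: independent action (noisy-OR),
   `I(h | C) = 1 − Π_{p ∈ C} (1 − v_eff)`. This is the standard null
   model for co-infection: it is exact when phages kill independently,
   reduces correctly at the anchors (a phage with `v_eff = 1` gives
   complete lysis; the empty cocktail gives 0), and is monotone under
   cocktail growth whenever the QPPIN is neutral.

Neither rule is uniquely determined by pairwise data — how three-way
interactions compose, and what "predicted growth inhibition" means
exactly, are genuinely open — so both are package policy, stated here
and exercised by the property tests rather than assumed.

A cocktail evaluation collects: per-host inhibition, **coverage**
(hosts with `I > τ`), **total inhibition** `Σ_h I`, **antagonism
burden** `Σ_{p≠q∈C} max(0, 1 − w(p, q))` (both directions of a pair
count — in a directed matrix both are real interference), **mean
redundancy** (lysing phages per covered host) and each virus's
**marginal contribution** `I_total(C) − I_total(C∖{p})`. Note that in a
directed QPPIN a phage silenced by a lethal partner can still have a
non-zero (even negative) marginal contribution if it, in turn, affects
its partners; its contribution is exactly zero when it is also neutral
toward them.

## Ranking and the two designers

Cocktails are compared by a deterministic total order. `coverage_first`
ranks by coverage (desc), antagonism burden (asc), total inhibition
(desc), then size (asc) — the "broad host range, minimal antagonism"
strategy; `virulence_first` puts total inhibition first. Under the
default redundancy policy (`minimize_excess`, target `r* = 2`) the
co-infection excess `Σ_h max(0, count_h − r*)` breaks remaining ties,
and the final tie-break is the lexicographically smaller virus list, so
results are reproducible to the byte. The `require_min` policy instead
*filters* candidates to those with at least `r*` lysing phages on every
covered host that the full network could cover `r*` times — the
"at least two phages per host" school of cocktail design.

**Exhaustive search** enumerates every subset up to the size cap
(default 12 phages, a cap motivated by horizontal-gene-transfer risk,
dysbiosis and production cost; it is a cap, not a target — smaller
winners are preferred by the size tie-break). It is optimal under the
ordering and refuses to start if the subset count exceeds the
enumeration budget (default 5·10⁶), pointing to the heuristic instead.

**Greedy network-metrics search** adds, at each step, the phage with the
largest resistance-weighted gain `Σ_h (1/d(h)) · [I(h|S∪{p}) − I(h|S)]`,
where `d(h)` counts the phages lysing `h` in the pruned network. The
`1/d(h)` weight is the standard rare-element prioritisation of greedy
set cover: hosts killable by few phages dominate the choice. Selection
stops at the cap or when no phage adds positive weighted gain. The exact
scoring of the heuristic is a reconstruction from its stated
ingredients (host-range breadth and host resistance profiles) and is
labelled as such; the guarantee that matters — greedy coverage never
exceeds the exhaustive optimum, and equals it on modular instances — is
asserted in the test suite.

Before either search, `pruneNetwork()` drops phages with empty host
range and flags uncoverable hosts; both are reported, and uncoverable
hosts never enter coverage counts. Rotation series
(`designCocktailSeries()`) re-run the search after excluding all
previously used phages, so the series is strictly phage-disjoint —
the point of rotation being that resistance evolved against one cocktail
should not pre-adapt hosts to the next. The series stops early, with a
warning, when the remaining phages cover nothing.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `maxSize` | 12 | hard cap on cocktail size (phages) |
| `tau` | 0 | infection threshold; any positive strength is an interaction, since 0 is defined as "no lysis" |
| `objective` | `coverage_first` | ranking mode |
| `redundancyMode` / `redundancyTarget` | `minimize_excess`, 2 | co-infection policy |
| `enumerationBudget` | 5e6 | exhaustive-search subset limit |

`tau` also drives the descriptive statistics: fill, binary entropy
`H(f) = −f log₂ f − (1−f) log₂(1−f)` (0 at the empty and saturated
extremes, 1 bit at half fill — a direct measure of how combinatorially
hard the design problem is), density (edges per node over the bipartite
node set — the natural reading when the node set is not otherwise
fixed), host range, and the two virulence means. Mean virulence is
reported both over all hosts and over infected hosts only, because the
virulence/host-range trade-off can be read either way; reporting both
costs nothing.

## The worked example

```{r}
fx <- workedExampleFixture()
as.matrix(fx$qpbin)
```

Phages 1 and 2 share a binary host range but phage 1 is stronger;
phages 6–8 are interchangeable narrow-range phages; phage 3 alone spans
hosts b3–b5 but antagonises (and is antagonised by) everything else with
factor 0.2. The quantitative design avoids it:

```{r}
res <- exhaustiveSearch(fx$qpbin, fx$qppin, designConfig(maxSize = 3))
res@overallBest$cocktail
res@overallBest$evaluation
```

while the binary view happily returns the minimum cover
`{phage3, phage1}` — whose quantitative total inhibition is only 0.64.
The fixture's numbers are constructed (round, minimal, hand-checkable),
not measured; what makes it trustworthy is that the test suite verifies
both outcomes by brute force over all subsets.

## Synthetic networks

`randomQPBIN()` occupies each cell independently with the target fill
and draws strengths uniformly on (0, 1]; `randomQPPIN()` makes each
unordered pair antagonistic/synergistic/neutral with the given
probabilities, drawing each direction separately. Defaults (fill 0.3,
20% antagonistic, 10% synergistic pairs in the test instances) reflect
that most experimental infection matrices are sparse and interference is
common but not dominant. All randomness flows through R's Mersenne-
Twister generator inside a local seed scope, so a seed fully determines
the matrix on any platform and generation never perturbs the caller's
RNG stream. By default all-zero rows/columns are resampled away (they
would be pruned anyway); `allowEmpty = TRUE` keeps them for pruning
tests.

What the generators deliberately do **not** emulate: the nested and
modular structure of real phage–bacteria networks, correlated
virulences, or measurement noise. Passing tests on these instances
therefore demonstrates algorithmic correctness (optimality, bounds,
determinism, round-trips), not predictive validity on real panels —
that depends on the quality of the measured QPBIN/QPPIN.

## Numerical and scale choices

Effective virulences and inhibitions are clamped into [0, 1]; ties in
the greedy gain are broken toward the lexicographically smaller virus
name (with a 1e-12 guard against floating-point near-ties); reports
render all numbers with 4 decimals so repeated runs diff cleanly.
Matrix round-trips are guaranteed to 6 significant digits. The test
suite sizes are desk-scale by design: oracle comparisons use 100 random
networks of up to 10 viruses × 8 hosts with cocktails up to size 4
(≤ 385 subsets each), the invariant sweep draws on the order of 10⁴
random checks, and the worked example needs 92 subsets — sizes chosen
so the full suite documents the method's properties in seconds.

## Limitations

* Pairwise factors cannot express genuinely higher-order interference;
  the multiplicative composition is an assumption.
* The model is static: no kinetics, no burst-size/latency dynamics, no
  resistance evolution during treatment.
* `require_min` can make every size infeasible on sparse networks; the
  result then reports only the feasible sizes.
* Exhaustive search is exponential; beyond the budget the greedy
  heuristic is the supported path, with no optimality guarantee beyond
  the dominance bound.
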