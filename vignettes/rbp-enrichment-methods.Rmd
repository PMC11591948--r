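---
title: "Ranking splicing-regulatory RBPs: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking splicing-regulatory RBPs: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery behind `spliceRBP`, the
assumptions each method makes, the numerical and design choices that were
genuinely open, and what the simulation-based tests do and do not
demonstrate about real data.

## The indicator matrix

Everything starts from the sparse binary matrix **E × S** with
`y[i, j] = 1` when a binding interval of RBP *j* intersects a defining
interval of splicing event *i* after each event interval is widened by
`window_nt` nucleotides on both sides.

Choices worth knowing about:

* **Coordinates.** All files use BED-style 0-based half-open intervals.
  Internally intervals live in `GRanges` (1-based closed, the Bioconductor
  convention); conversion happens once at the file boundary, so the overlap
  semantics on disk are exactly half-open — a site that *ends* where a
  widened event region *starts* does not overlap, and the tests pin this
  boundary down to one base.
* **Window anchoring.** `window_nt` (default 400) widens *every*
  event-defining interval, not a window around a single representative
  splice-site point. Events are multi-interval genomic regions; anchoring
  at interval ends is the least arbitrary reading of "within a window of
  the event" and is monotone in the window (the tests verify the nonzero
  set can only grow as the window grows). Anyone needing bit-exact
  agreement with a matrix built by point-anchored windows should rebuild
  from intervals, not compare matrices.
* **Strand.** CLIP peaks and events are both stranded, but source
  annotations disagree often enough that strand-blind overlap
  (`strand_mode = "ignore"`) is the default; `"match"` is available, with
  `"."` matching anything.
* **Binding redundancy.** Multiple CLIP experiments per RBP are pooled and
  merged into one interval set per RBP. For a binary indicator the merge
  changes nothing downstream; it simply makes the collection canonical and
  order-insensitive.
* **Affinity.** The BED score column is read and discarded. The matrix is
  deliberately binary: every downstream model treats binding as an
  indicator, not a dose.

## Universe and selection

The analysis universe (size *M*) is the set of events present in **both**
the matrix and the stats table, aligned to a common order. Defining *M* as
tested-events-only (rather than all annotated events) is required for the
contingency counts to be coherent: every event counted must have both a
binding row and a p-value.

Selection of the "differentially spliced" set (size *K*) supports three
rules: raw `pvalue < 0.001` (strict inequality — the default), the 1000
smallest p-values (stable sort, ties broken by event id so reruns are
reproducible), or BH-adjusted `p <= level`. The BH step-up itself is
`stats::p.adjust`.

## Fisher / hypergeometric test

With *m* events bound by an RBP and *k* of them selected, the p-value is
the upper tail `P(X >= k)` of Hypergeom(M, m, K), inclusive of *k*, with
`k = 0` returning exactly 1. One-sided enrichment only; depletion is not
interesting here and is not reported. The implementation delegates to
`stats::phyper`, which is already computed stably in log space; tests
verify it against direct rational-arithmetic tail summation on the full
parameter grid up to `M = 30` (where every binomial-coefficient product is
an exactly representable integer) at 1e-12.

The test's hidden assumption is exchangeability: every event equally
likely to be bound, every RBP equally promiscuous. Real indicator matrices
violate both, which motivates the next method.

## The margin-matched background model and the Poisson-Binomial test

The background model assigns each cell an independent Bernoulli
probability `p_ij = plogis(mu_i + lam_j)` — a logistic main-effects model
whose maximum-likelihood solution is characterized by margin matching:
expected row and column sums equal observed ones. The fit is coordinate
ascent with vectorized Newton updates, exploiting two structural facts:

* The stationarity condition for `mu_i` depends on the data only through
  the row sum, so **rows with equal sums share one effect** (and likewise
  columns). The fit therefore runs on unique margins — at most S+1 row
  groups and E+1 column groups — and converges in a handful of sweeps even
  at 5000 × 244.
* No operation ever materializes the dense E × S probability matrix;
  `model_prob()` evaluates `p_ij` on demand from the effect vectors.

Numerical details: Newton steps are clamped to ±5 per inner iteration (the
1-D problems are concave, so this only slows, never breaks, convergence);
identifiability is fixed by anchoring the count-weighted mean of `lam` at
0; convergence is declared when the maximum absolute margin error drops
below `tol` (default 1e-6), and non-convergence within `max_iter` sweeps
is an error carrying the fit report. Degenerate margins cannot have finite
ML effects, so all-zero rows/columns are held out with probability exactly
0 and all-one ones with probability 1, peeled iteratively; where a zero
and a one margin cross, zero wins (the convention is arbitrary but must be
fixed; it preserves the observed margins of the peeled rows).

The enrichment p-value for an RBP is then the Poisson-Binomial upper tail
of the observed bound-selected count against the selected events'
`p_ij`. The tail is computed by exact dynamic-programming convolution —
the count distribution is multiplied by one Bernoulli factor at a time,
entirely in linear probability space, where every intermediate value lies
in [0,1] and the tail sum cannot underflow meaningfully — for up to
`dp_limit = 5000` probabilities (seconds of work; the boundary is a
configuration knob, not a hard limit). Beyond it a refined normal
approximation with skewness correction takes over, and the method used is
recorded in the output. On a matrix with exactly constant margins the
model collapses to `p_ij = density` and the Poisson-Binomial tail to a
plain binomial tail, which is how the bias correction is validated: on
constant-margin matrices the Fisher and Poisson-Binomial rankings agree
essentially perfectly, so any disagreement on real data is attributable
to margin heterogeneity, which is exactly what the correction is for.

## Pre-ranked GSEA

Events are ranked by `s = -log10(p)` descending (p = 0 clipped to the
smallest positive double; ties broken by event id). The enrichment score
is the signed extreme deviation of the running sum that adds
`|s|^weight / (total hit weight)` at bound events and subtracts
`1/(M - m)` elsewhere; `weight = 1` by default, `weight = 0` recovers the
classic unweighted statistic. Since extremes can only occur immediately
before or after a hit, one placement costs O(m log m), and the permutation
null — uniform random placements of the m hits among the M ranks,
implemented in C++ on R's RNG stream so `set.seed()` reproduces it —
evaluates tens of thousands of placements per second.

The one-sided p-value is `(1 + #{ES_perm >= ES_obs}) / (1 + n_perm)`.
When the estimate falls below `10 / n_perm` the permutation count is
escalated tenfold up to `max_perm`, so top-ranked RBPs keep relative
resolution; the floor `1/(n_perm_used + 1)` is implied by the +1
smoothing, and downstream ranking breaks floor ties by |ES|. The
multilevel split Monte-Carlo scheme used by `fgsea` for arbitrarily small
p-values is deliberately out of scope — for ranking a few hundred RBPs,
escalation plus the ES tie-break is sufficient and much simpler. The
ranking metric (unsigned `-log10 p`, weight 1) and the permutation scheme
(hit-label permutation, not sample permutation) are package decisions;
neither choice is canonical across GSEA implementations, so both are
stated here explicitly.

## Wilcoxon rank-sum

The ranks of all M p-values (average ranks under ties, tie-group sizes
recorded) are computed once; the per-RBP rank sums of bound events for
*all* RBPs are one sparse crossproduct `t(Y) %*% r`, so the whole test is
O(nnz). The p-value uses the normal approximation with the tie-corrected
variance `m n / 12 * ((M+1) - sum(t^3 - t)/(M(M-1)))` and continuity
correction 0.5 — the same formulas as `stats::wilcox.test(exact = FALSE,
correct = TRUE)`, which the tests use as the per-column oracle at 1e-10.
No exact small-sample version is provided; columns with fewer than five
bound events are flagged `low_confidence` instead. Default sidedness is
`"less"` — enrichment means bound events' p-values are stochastically
smaller — with `"greater"` and `"two_sided"` available; the choice of a
one-sided default mirrors the other three methods, all of which test
enrichment only.

## Ranking, percentiles, aggregation

Within a method, RBPs are stably sorted by (p-value, |statistic|
descending, name); the percentile printed next to a rank is
`floor(100 * (1 - rank/S)) / 100` — a fixed, deterministic convention
(rank 1 of 244 prints 0.99; the last rank prints 0.00) chosen so that
reports are reproducible rather than dependent on a rounding mode.
Cross-condition aggregation calls an RBP enriched in a
condition when its BH-adjusted p-value is at or below 0.05 (configurable)
and reports RBPs recurring in at least `min_conditions = 5` conditions,
boundary inclusive.

## What the simulator emulates — and what it does not

`simulate_exs()` draws effects `mu ~ N(-3, 0.6)`, `lam ~ N(0, 0.6)` and
independent Bernoulli cells, giving ~5% mean density with realistic
row/column heterogeneity at the default 5000 × 244 scale — the size of an
event universe tested against a pooled CLIP compendium.
`simulate_knockdown()` gives events bound by the designated target RBP
Beta(0.1, 1) p-values (mean 1/11; a = 1 recovers the uniform null) against
a Uniform(0, 1) background, and |ΔΨ| in [0.1, 0.6] for signal events. The
signal is injected through the target's own binding column, so RBPs with
correlated columns can legitimately rank high — the same behaviour
co-binding factors show in real knockdown validations — and no attempt is
made to decorrelate them.

What passing these tests shows: the four statistics, their null
distributions and the ranking machinery are implemented correctly, and
under a strong, well-specified knockdown all four methods recover the
causal RBP at rank 1 in ≥ 90% of seeds (top 10% in all). What it does not
show: robustness to mis-specified binding data (CLIP peaks are noisy and
condition-specific), to correlated event statistics (events within one
gene are not independent), or to selection rules interacting with p-value
calibration of the upstream caller. The Bernoulli-independence assumption
of the background model is itself an idealization; on real matrices it
corrects margin bias but cannot model residual dependence.

## Problem sizes and runtime choices

The test suite exercises: exact Poisson-Binomial tails against 2^n
enumeration (n ≤ 12) and binomial closed forms (n ≤ 1000); the full
hypergeometric grid M ≤ 30; model fits at 200 × 50 and 2000 × 244 with
margin error < 1e-6; Fisher/Poisson-Binomial rank agreement over 50
constant-margin instances; the rank-sum oracle over 200 instances plus a
2000-column type-I experiment; GSEA against exhaustive placement
enumeration at M = 10, m = 3 with 1e5 permutations; and 20 knockdown
recovery seeds at 5000 × 244 with 2000 GSEA permutations per RBP. These
sizes keep a full run in a few minutes on one core while leaving every
statistical comparison at its stated tolerance; GSEA permutation counts
are the one knob a user with more cores or patience should raise first
(the default in `gsea_enrichment()` is 1e4 with escalation to 1e6).

## Known limitations

* Event *calling* and Ψ estimation are upstream; garbage in, garbage out.
* Binding is binary: no affinity weighting, no per-experiment columns.
* The Poisson-Binomial test corrects margin bias only; systematic
  co-binding structure beyond margins is not modelled.
* GSEA p-values are floored by the permutation budget; two RBPs at the
  floor are ordered by |ES|, which is a heuristic.
* The normal approximation of the rank-sum test is inaccurate for very
  small m (flagged, not fixed).
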