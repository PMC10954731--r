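---
title: "Chain functions in Boolean models of gene regulation: counting, enrichment and model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain functions in Boolean models of gene regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncfchain)
```

## The model

A Boolean network represents each gene as an on/off variable updated
synchronously by a regulatory logic rule, a Boolean function (BF) of its
regulators.  `ncfchain` is about a hierarchy of function classes that
empirically dominate reconstructed models of real gene regulatory networks
(GRNs):

* **Nested canalyzing functions (NCFs)**: rules that can be peeled input by
  input — at every stage some input has a *canalyzing* value that alone
  fixes the output, and the recursion continues on the other value's
  half-table.  Peeled inputs group into *layers* (maximal runs with the same
  canalyzed output); the layer sizes `m_1..m_last` are determined entirely
  by the pair (number of inputs `k`, bias `P`), where the bias is the count
  of 1s in the output column.  NCFs always have odd bias, and the first
  `k - 1` bits of the k-bit binary form of `P` spell the AND/OR operator
  sequence of the nested expression (0 = AND, 1 = OR).
* **Chain-0 functions**: NCFs admitting a peeling whose first `k - 1`
  canalyzing input values are all 0 (the last input canalyzes in both
  values).  In expression form, every positive literal is followed by AND
  and every negative literal by OR, with at most one sign-deviant variable
  in the last layer.
* **Chain-1 functions**: the dual class — canalyzing values all 1;
  equivalently the image of the chain-0 class under negating every
  variable.
* **Generalized chain functions**: the union of the two.  The classes are
  disjoint from `k = 3` on; for `k <= 2` they jointly exhaust the NCFs, so
  "chain vs NCF" comparisons are meaningless there and every routine flags
  that regime instead of reporting a number.

## Counting and the constant C

Per bias, `|NCF|_{k,P} = 2^k k! / (m_1! ... m_last!)` and
`|ChF0|_{k,P} = k! (1 + m_last) / (m_1! ... m_last!)`; their ratio collapses
to `(1 + m_last)/2^k` (`fraction_chain_in_ncf()`).  Totals over odd biases
are computed without touching the `2^(k-1)` biases individually: odd biases
correspond two-to-one to compositions of `k` with last part at least 2, and
`count_ncf()` / `count_chain()` evaluate the composition sums with a
head-part recursion (`A(j) = sum_m C(j,m) A(j-m) + 1`, and a
`(1 + m_last)`-weighted twin `W`).  The chain share of NCFs factorizes as
`C(k)/2^k` with `C(k) = W(k)/A(k)` trapped in `[3, k+1]`; it converges
rapidly:

```{r constant}
chain_fraction_constant(30)$value_str
```

All counts use an internal exact big-integer layer (base-1e7 limbs), so the
13-plus significant digits of that constant and counts of order 10^10 carry
no floating-point error; doubles appear only when a value is rendered.  The
dynamic programme covers `k` up to 200 in well under a second; per-bias
operations that must represent `P` exactly are limited to `k <= 50`.

## Classification choices

* **Row convention**: truth-table row `r` (0-based) encodes the assignment
  whose bits, most-significant-first, are `(x_1, ..., x_k)`.  The integer
  encoding with row 0 as the most significant bit is called
  `integer-msb-row0` in the file readers; both endianness dialects are
  readable because public BF collections do not agree on one.
* **Greedy peeling** with lowest-index tie-breaking is the production
  classifier.  Within a layer every input canalyzes simultaneously, so the
  greedy choice cannot miss a chain peeling; an exhaustive search over peel
  orders is retained as an internal oracle and the test suite asserts
  equality on all functions up to `k = 3` plus random and in-class samples
  at `k = 4, 5`.
* **Degenerate inputs**: constants and functions with dummy (inessential)
  inputs are `NOT_NCF` — every input of an NCF must canalyze.  Both 1-input
  non-constant functions are labelled `CHF_BOTH`, since the "last input
  canalyzes in both values" clause is the only applicable one at `k = 1`.
* `build_ncf()` canonicalizes chain deviants by position rather than by a
  printed normal form: within the last layer, variables commute with their
  signs, so any single-deviant expression equals one of the `1 + m_last`
  canonical builds.

## Enrichment statistics

For an englobing type `T` (here NCF) and sub-type `T_s` at fixed `k`, the
relative enrichment is `E_R = (f_s1/f_1)/(f_s0/f_0)` — dataset fractions
over theoretical fractions.  Significance is the inclusive upper binomial
tail of the `T_s` count among the dataset's `M_T` type-`T` members at
success probability `f_R = |T_s|_k/|T|_k`, with `f_R` taken from the exact
counts, not sampled.  No continuity correction and no multiple-testing
adjustment are applied, matching how such enrichment tables are usually
reported.  Because the binomial test is discrete, its attained size at
threshold 0.05 is slightly below 0.05 (0.0464 at `k = 4` with 200 draws per
replicate, the configuration the calibration test uses; that size is a
deterministic property of the test, computed, not tuned).

## Dynamics and relative stability

Noisy dynamics flip each node independently with probability `eta` per
step; if no flip occurs the deterministic synchronous image is applied.
The one-step law is the column of `T* = (1-eta)^N T + P` with
`P_lm = eta^d (1-eta)^(N-d)` over Hamming distances `d >= 1`.  The mean
first passage time `M_uv` (steps to first reach cell state `u` from `v`)
defines relative stability `RS(u,v) = 1/M_uv - 1/M_vu`; `u` is the more
stable state when positive.

Numerical choices:

* `eta` defaults to 0.05 and 3000 trajectories per MFPT; hierarchy verdicts
  are insensitive to `eta` in the 0.01-0.05 range (asserted on fixtures).
* Exact MFPTs via the absorbing-chain linear solve are used whenever
  `N <= 12`; they remove sampling noise and serve as the oracle for the
  sampled estimator.  Above that, batched trajectory sampling is used, with
  a per-(model, pair) seed derived from a master seed so results do not
  depend on evaluation order.
* Trajectories are capped at `max_steps` (default 1e6) and overruns are
  reported as failures, never silently dropped.  Sampled RS values within
  3 standard errors of zero are reported as "undecided" and fail a
  hierarchy constraint rather than passing it.
* State bit order is node declaration order, most significant first; this
  is a pure convention and is fixed everywhere (files, states, printing).

## Model selection

Starting from a signed GRN and named biological fixed points,
`node_constraints()` + `admissible_functions()` generate each node's
admissible rules: class members that reproduce every fixed point row-wise
and whose literal signs match the edge signs.  For NCFs the literal sign
equals the unate direction, so sign conformity on the constructive form and
on the truth table coincide; the constructive path (odd bias, layer
structure, sign-compatible layer assignment, optional last-layer deviant)
is verified against brute-force filtering of the enumerated classes.  A
node whose class admits nothing can fall back to a broader class (the
NCF fallback mirrors how such dead-ends are handled in practice).  The
ensemble is the cartesian product; `select_models()` screens
attractors/basins first (cheapest), then evaluates MFPT hierarchies, and
keeps models whose hierarchy verdicts all hold, whose biological basin sum
reaches the reference floor, and (optionally) which have no spurious
attractors.

## What the synthetic generators emulate — and what they do not

`synthetic_bf_dataset()` plants class mixtures with per-k weights,
emulating a curated collection of regulatory rules with known ground truth;
`random_model()` plants sign-conforming class-constrained networks whose
fixed points are computed exactly.  These fixtures share the *statistical*
structure of reference datasets (class frequencies, odd-bias dominance,
sign consistency) but none of their biological correlations: real
collections are not uniform within a class, input counts correlate with
gene function, and curators' stylistic biases are absent.  Passing the
planted-recovery and calibration tests therefore validates the machinery,
not any claim about real data.

Test problem sizes are chosen to keep the whole suite desk-scale: full
2^(2^k) classification up to `k = 4`, enumeration cross-checks at
`k = 5, 6` (the classes grow combinatorially; NCFs at `k = 6` already
number 183,936), planted-recovery over 50 random networks of 4-6 nodes
with exact MFPTs, and 2000-replicate calibration.  The planted-recovery
test evaluates bounded sub-ensembles that always contain the generating
model; selection is per-model, so membership of the generator in the
selected set is unaffected by the truncation.

## Known limitations

* Enumeration (`enumerate_class`) is capacity-limited (NCFs to `k = 8`,
  chains to `k = 10` as hard caps) and intended as an oracle and sampling
  pool, not a bulk generator; counting has no such limits.
* Only synchronous updating is implemented; asynchronous schemes change
  basins and MFPTs and are out of scope.
* Exhaustive selection refuses ensembles beyond 1e6 models; larger
  ensembles call for cluster-scale runs or stochastic search, neither of
  which this package attempts.
* The binomial enrichment test conditions on the observed number of NCFs
  per `k` and assumes independent draws; rules extracted from the same
  publication are not independent in real collections.
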