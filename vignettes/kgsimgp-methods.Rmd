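---
title: "Methods: aspect-wise semantic similarity and evolved combinations"
author: "kgsimgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aspect-wise semantic similarity and evolved combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgsimgp)
```

## Overview

`kgsimgp` treats an annotated corpus as a knowledge graph: entities
(proteins) are linked to terms of a multi-rooted *is-a* ontology (the Gene
Ontology's three aspects being the motivating case). For a pair of
entities the package computes one semantic-similarity score per aspect,
and a supervised layer — genetic programming over expression trees — learns
how to combine the aspect scores into a binary classifier for pair-level
outcomes such as protein–protein interaction. This vignette records the
model, the assumptions, and the design decisions a maintainer would want
to know; the README shows the user-facing workflow.

## The ontology model and its assumptions

Only *is-a* edges are used. Each aspect must be a rooted sub-DAG: a root
is a term without parents, and every term must reach exactly one root;
violations (cycles, multi-root terms) are structural errors at parse time,
not warnings, because every downstream quantity assumes aspect-disjoint
DAGs. Other relation types (`part_of`, `regulates`) are parsed only on
request and are excluded by default — cross-relation reasoning changes the
semantics of ancestor sets and is out of scope. Obsolete terms are
dropped; `alt_id`s are mapped to their canonical term so that annotation
files written against older ontology releases still resolve.

Ancestor sets are reflexive (`A(t)` contains `t`). This is the standard
MICA convention and is what makes `sim(t, t) = IC(t)` and makes the
similarity of identically annotated entities maximal.

## Information content

The intrinsic (structure-only) IC follows the descendant-count form:
`IC(t) = 1 − log(hypo(t) + 1) / log(maxnodes)` with `hypo(t)` counting the
descendants of `t` including `t` itself. Two choices here were genuinely
open:

* **`maxnodes` is per-aspect by default.** Each aspect is an independent
  rooted sub-DAG and similarities are computed within aspects, so the
  natural normalization is the aspect's own term count.
  `compute_ic(per_aspect = FALSE)` switches to whole-graph normalization
  for users who prefer a global scale; per-aspect remains the default.
* **The root's IC is clamped to 0.** As printed, the formula gives the
  root a slightly negative value (`hypo(root) + 1 > maxnodes`). Clamping
  preserves the documented `[0, 1]` range of every IC, keeps SimGIC
  bounded in `[0, 1]`, and loses nothing (a root carries no information).
  The unclamped value is available via `compute_ic(clamp = FALSE)`.

On the four-term toy ontology (root `R`, children `A`, `B`, leaf `C`
under `A`) these give `IC(B) = IC(C) = 0.5`, `IC(A) = 1 − log 3 / log 4 ≈
0.2075`, `IC(R) = 0` — values small enough to verify by hand, and frozen
in the test suite.

## Entity similarity

Three measures are implemented, all symmetric and bounded in `[0, 1]`:

* **SimGIC** uses *extended* annotation sets (direct terms closed under
  ancestors), as an IC-weighted Jaccard index.
* **ResnikMax / ResnikBMA** use *direct* annotation sets and aggregate
  pairwise MICA similarities by maximum or best-match average. Whether the
  original pairwise variants extended the sets is not documented anywhere
  authoritative; direct-only is the field's standard for pairwise
  measures and is the default, with `mode = "extended"` available on both.
* The best-match average is implemented as its name says: each term is
  matched to its best partner on the other side, and the two directional
  sums are normalized by twice the respective set sizes. A literal reading
  of the printed double-sum formula (without the inner maximization) would
  not be a best-match average and is not implemented.
* An entity with no annotations in an aspect scores 0 in that aspect.
  This keeps the feature table total; pairs lacking annotations in *every*
  aspect are removed upstream by `filter_pairs()`, which implements the
  benchmark filtering rule (both entities annotated in at least one
  aspect).

Ancestor closures are precomputed once per graph. The test suite holds the
implementation to observational equivalence (1e-12) with a deliberately
naive oracle that re-enumerates ancestor sets on every call, on random
ontologies, so the caching is behaviorally invisible.

## The evolved combiner

GP evolves expression trees whose leaves are the aspect scores
(`X0` = BP, `X1` = CC, `X2` = MF for GO-like graphs) and real constants,
and whose internal nodes come from `{add, sub, mul, div, max, min}`.
Division is protected: denominators of magnitude ≤ 1e-3 yield 1, keeping
every tree total and finite on the input cube.

Classification is regression-like: labels 0/1 are numeric targets, raw
RMSE is the fitness, and the reported fitness is always unpenalized.
Selection, however, minimizes `RMSE + c · nodes` with parsimony
coefficient `c = 1e-5` — enough to prefer the smaller of two equally fit
models without distorting the search. Prediction applies the fixed cutoff
`raw > 0.5`; ties at exactly 0.5 resolve to class 0. The cutoff is
deliberately not tuned — the point of the method is that the *combination*
adapts, not the threshold.

Defaults: population 500, 50 generations, tournament size 20, ramped
half-and-half initialization at depths 2–6, crossover 0.9 and
subtree/hoist/point mutation 0.01 each, point-replace probability 0.05,
ephemeral constants uniform on `[−1, 1]`. All are exposed in
`gp_params()`. Crossover and mutation points are drawn with the classical
90/10 bias toward internal nodes; in development this was measurably
better at structural search than uniform node choice. Offspring deeper
than `max_depth` (default 17) are replaced by their parent, a mild bloat
guard that leaves typical runs untouched.

Determinism: `evolve()` takes an explicit seed, saves and restores the
caller's RNG state, and two runs with the same seed return identical
models. The same holds for every generator in the package; nothing uses
global random state.

A note on search difficulty: when the true rule is a thresholded
combination whose boundary does not sit at the 0.5 cutoff (e.g.
`max(BP, CC) > 0.6`), the unshifted combination `max(X0, X1)` is a strict
local optimum of the RMSE landscape — every single-edit change (shifting
by a constant, scaling, squaring) has worse RMSE, and escaping requires a
coordinated multi-node jump such as `2·max(X0, X1) − 0.7`. Vanilla GP at
small budgets (population 200, 30 generations) escapes in roughly a third
of runs on uniformly distributed features. On features produced by the
package's own generator the ambiguity band around the cutoff carries much
less probability mass, and recovery at those budgets is reliable; this is
the configuration the acceptance checks exercise.

**Simplification** is conservative by design: identity and annihilator
rules, constant folding under the protected-division semantics,
self-cancellation (`x − x`, `x ÷ x`), and max/min idempotence, iterated to
a fixed point. No distribution laws over max/min are applied, so the
rewritten tree can always be verified pointwise-equal to the original by
random probing (the tests probe 1000 points at 1e-9). Model statistics
(node count, per-variable leaf shares) are computed after simplification,
so redundant code does not inflate them.

## Baselines and evaluation

* **Static combinations** (each aspect, average, maximum) select their
  threshold by scanning 0–1 in steps of 0.01 on the training set and
  keeping the smallest threshold that maximizes training WAF. The 0.01
  step is finer than the grid search below, cheap, and reproducible.
* **Grid search** enumerates all weight triples on the 0.1 grid (11³ − 1 =
  1330, the all-zero triple being undefined for a weighted average) × 21
  thresholds on the 0.05 grid, classifying by `weighted mean > threshold`.
  Ties break to the first candidate in lexicographic
  `(w_BP, w_CC, w_MF, threshold)` order, making the winner deterministic
  under a fixed enumeration; the tests require exact agreement with an
  independently coded full enumeration.
* **Decision tree**: a thin adapter over `rpart` (CART) with default
  parameters — a comparison baseline, not a reimplementation target. Its
  internal cross-validation consumes random numbers, so the adapter seeds
  it for reproducibility.
* **WAF** is the support-weighted mean of per-class F-measures; a class
  with an undefined precision or recall contributes F = 0 (the standard
  zero-division convention, which keeps WAF defined on degenerate folds).
* **Stratified k-fold**: within each class, indices are shuffled and dealt
  round-robin around the fold ring, with the dealing cursor continuing
  across classes. This keeps per-class fold counts proportional within ±1
  *and* total fold sizes even — both properties are needed for small
  unbalanced datasets, and neither round-robin-per-class-from-fold-1 nor
  independent remainder spreading achieves the two together. Classes
  smaller than `k` are allowed (they simply miss some folds); only fewer
  observations than folds, or single-class labels, are errors.
* **Pairs are unordered** everywhere: datasets store each pair in
  canonical id order, duplicate (pair, label) rows are dropped at load,
  and cross-dataset deduplication removes the overlap from the *training*
  side by default — the reported test set stays intact. The removal side
  is configurable.
* **Method comparison** uses the two-sample Kruskal–Wallis rank test on
  per-fold scores at α = 0.01, with tie handling delegated to
  `stats::kruskal.test`; two identical constant score vectors are reported
  as statistic 0, not significant.

## The synthetic generator

The generator emulates the statistical shape the method assumes, not real
GO topology. Defaults are fixed once as the package's study conditions:
three aspects sized 100/80/60 (the process aspect largest, as in GO), each
new term attaching to 1–3 earlier terms of its aspect, 100 entities,
annotation probability 0.9/0.9/0.8 per aspect with 1–5 direct terms drawn
with weight proportional to IC, labels from `max(BP, CC) > 0.5` with 5%
flips, 1000 pairs. Leaf-biased term sampling spreads entity similarities
over `[0, 1]` — uniform term sampling concentrates similarity near 0 and
makes every classification task trivial or impossible. Lowering one
aspect's annotation probability reproduces the situation where a corpus is
poor in one aspect's annotations and that aspect's single-score baseline
degrades; the tests assert exactly that monotonicity.

Negative sampling is either uniform ("unbalanced") or degree-balanced:
negatives are greedily chosen so each entity's negative occurrences track
its positive occurrences (exact matching is a hard combinatorial problem;
the greedy matcher plus a recount check is sufficient for its purpose,
emulating degree-balanced benchmark design). Truth rules are written in
the same expression language as evolved models, so recovery experiments
compare like with like.

What passing synthetic tests does *not* show: real GO term-depth
distributions, annotation co-occurrence structure, evidence-code biases,
or identifier-mapping loss. Results on generated data demonstrate
pipeline correctness and recoverability, not expected field performance.

## Numerical choices, degenerate inputs, sizes

* Protected division threshold 1e-3 (returns 1), matching the documented
  protection convention of the reference GP tooling.
* Similarity oracle tolerance 1e-12; simplification probe tolerance 1e-9;
  IC comparisons 1e-14. Grid-search scan arithmetic mirrors the scalar
  WAF routine operation for operation so scans and naive recomputation
  agree bitwise.
* Single-class training labels: error by default; `gp_params(on_single_class
  = "constant")` returns the constant majority model with a warning.
* Empty annotation aspects score 0; unknown entities yield empty sets so
  filtering can run before feature computation, which *requires* filtered
  input and treats unannotated entities as contract violations.
* Test and acceptance problem sizes were chosen as the smallest that
  exercise the claims crisply: brute-force cross-checks on ontologies of
  ≤50 terms per aspect and ≤20 entities; GP recovery at population 200 and
  30 generations on 1000 pairs; 10-fold cross-validation on the default
  1000-pair study.

## Known limitations

Only is-a reasoning; no corpus-based (extrinsic) IC; no other similarity
measures (Lin, Jiang–Conrath, Wang) or truncation heuristics; no
multi-objective or strongly-typed GP, no linear scaling, and no evolved
cutoffs. OBO parsing covers the flat-file subset the package writes and
the common tags of public releases (`id`, `name`, `namespace`, `alt_id`,
`is_a`, `relationship`, `is_obsolete`); OWL is out of scope. The GAF
reader keeps all evidence codes by default — evidence filtering is
available but no curated default is imposed.
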