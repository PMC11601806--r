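---
title: "Subsplit DAGs and systematic NNI search: models and methods"
author: "sdagsearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subsplit DAGs and systematic NNI search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdagsearch)
```

## The problem

Bayesian phylogenetics asks for a posterior distribution over tree
topologies, but MCMC explores that space by a random walk whose substantial
moves are mostly rejected. Maximum-likelihood search is systematic but
characterizes only a point estimate. This package implements a middle road:
represent *many* rooted topologies at once in a subsplit directed acyclic
graph (sDAG), and grow that structure systematically with
nearest-neighbor-interchange (NNI) operations until it covers a
high-posterior-density region of topology space. The goal of a search is a
*small* sDAG whose topology set captures most of the posterior mass.

## The subsplit DAG

Fix an ordered taxon set. A *clade* is a subset of the taxa; a *subsplit*
is an ordered pair of disjoint clades, the label of an internal node: it
records how the taxa below that node bipartition. Leaf subsplits pair the
empty clade with a singleton, and a universal ancestor node (rho) pairs the
empty clade with the full taxon set. Edges connect a parent subsplit to a
child subsplit that partitions one of the parent's clades, so an edge is
identified by the triple (parent, clade side, child) — the unit that carries
a branch length.

Any single rooted bifurcating topology is an sDAG (a chain of such edges);
an sDAG built from several topologies is the union of their node and edge
sets. Tree-structured subgraphs containing all leaves are exactly the
topologies the sDAG *contains* — typically more than were used to build it,
which is the point: the support is expanded combinatorially. Because each
edge carries one branch length, topologies in the sDAG correspond one-to-one
to trees.

Clade order. The package orders clades by putting the empty clade first and
otherwise comparing membership vectors along the taxon order (the clade
containing the earlier taxon at the first disagreement is smaller). The
empty-minimum convention makes the degenerate subsplits uniform: rho and the
leaf subsplits all carry their content on the right, and edges out of rho
always partition the right clade. Any total order extending the taxon order
would do; this one is deterministic, cheap, and gives a canonical "lesser
clade on the left" form for every subsplit.

### Distributions on topologies

Assigning a probability vector to the outgoing edges of every
(node, clade) pair makes the sDAG a normalized distribution over the
topologies it contains: a topology's probability is the product of its
edges' conditional probabilities. Fitting from a topology sample is by
normalized frequency counts of child subsplits among sampled topologies
containing the parent. Conditional clade distributions (CCDs) are the
special case in which all parents sharing a clade use the same vector;
`isCladeConditional()` tests for exactly that, and the general sDAG form is
a strict generalization (it may condition on the sister clade).

## NNI as an enlargement

On a topology, an NNI swaps two subtrees across an internal edge. On an
sDAG the analogous move *adds* rather than modifies: for an edge from
`t = {X u Y, Z}` to `s = {X, Y}`, swapping `Y` with `Z` introduces
`t' = {X u Z, Y}` and `s' = {X, Z}`, and three classes of edges — (a) the
*central edge* `t' -> s'`, (b) a parent edge `u -> t'` for every existing
`u -> t`, and (c) descendant edges mirroring, clade by clade, the existing
children of `s` and of `t`'s swapped clade. Each eligible sDAG edge (parent
not rho, child not a leaf) yields two such proposals; proposals that add
nothing are discarded.

The searches maintain *edge-complete* sDAGs (an edge between every
compatible node pair). Under that invariant two structural guarantees hold,
and are enforced as test invariants here: every topology new to the
post-NNI sDAG contains the central edge, and every new topology is one NNI
away from a pre-NNI topology. After an NNI the result may again be missing
compatible edges incident to `t'` and `s'`, so application immediately
completes them; the top-pruning search completes the whole graph each
iteration, while the generalized-pruning search adds only edges touching
the new subsplits, following the two algorithms' differing prescriptions.

## Evaluating a proposal

Both criteria fix a single branch length per sDAG edge and use the
Jukes-Cantor substitution model with stationary root frequencies 1/4, no
rate variation, and likelihoods computed by Felsenstein pruning over
per-site partial likelihood vectors (PLVs). Branch lengths are optimized,
never marginalized.

**Top pruning.** Ideally one would score an NNI by the maximum, over all
trees through its central edge, of the tree likelihood — too expensive, as
it enumerates trees. Instead every edge carries a *choice map*: a rootward
selection (parent edge, sibling edge) and a leafward selection (left child
edge, right child edge). Recursively applying the choice maps from any edge
yields its *best known tree* (BKT), a deterministic proxy for the best tree
through that edge; the *top-pruning likelihood* of an NNI is the Felsenstein
log likelihood of the BKT of its central edge, with that edge's length
optimized. When an sDAG is built from a likelihood-ordered tree list, each
edge's length and choices come from the first listed tree containing it.

**Generalized pruning.** The GP criterion scores an NNI by a per-edge
topology-marginal *composite* likelihood: per site, the average of the site
likelihood over all trees through the central edge (uniform prior over that
tree set), multiplied across sites. It is computed by a two-pass dynamic
program whose PLVs are shared across topologies — a leafward pass
accumulating clade-sum vectors and a rootward pass accumulating
above-the-edge vectors — so cost scales with sDAG size, not with the number
of trees. The *true* marginal likelihood would average the whole-alignment
product per tree; it has no comparably efficient algorithm, and the package
provides it only as a brute-force enumeration (`trueMarginalBruteforce()`)
to document the distinction: the two coincide exactly when only one tree
passes through the edge or the alignment has one site, and differ otherwise.

The GP recursions here were derived from the factorization of the composite
sum over independent per-clade subtree choices, and their contract is
equality with the enumeration oracle `gpLikelihoodBruteforce()` (checked to
1e-9 over hundreds of randomized sDAGs), not fidelity to any particular
published recursion scheme.

### The search loops

Both searches: build the sDAG from a likelihood-ordered tree list, complete
compatible edges, assign the new edges' lengths by their own criterion,
rank all enlarging proposals, then repeatedly apply the best-ranked
proposal, extend choices/lengths, and insert newly enabled proposals with
freshly computed scores. Cached scores of queued proposals are *not*
refreshed when the sDAG changes — a deliberate fidelity choice, with the
consequence that pop order can rest on slightly stale values. Queued
proposals that have become non-enlarging by the time they are popped are
discarded without counting as an iteration. Iteration stops at a fixed
count or when every queued score falls below a threshold (an infinite
threshold performs no iterations, returning the completed initial sDAG).

One step of the generalized-pruning algorithm refers to a twice-enlarged
sDAG where only a once-enlarged one exists; the package reads it as the
once-enlarged sDAG (the straightforward reading of an apparent slip).

## Design choices where the design was open

* **Argmax choice-map extension.** How choices are assigned to
  completion-added and NNI-added edges is stated only as "an argmax
  strategy" in the source material available to us. The package resolves it
  slot-wise and greedily: seed every unset slot with its first candidate in
  canonical edge order, then for each new edge fill the parent+sibling pair
  (jointly), then the left child, then the right child, each by maximizing
  the BKT log likelihood of that edge; ties keep the earlier candidate.
  This is deterministic, evaluates full tree likelihoods (not a surrogate),
  and degenerates to the forced choice when only one candidate exists.
* **Lengths inside an NNI evaluation.** Only the central edge's length is
  optimized when scoring a top-pruning proposal; other new edges inherit
  the length of their pre-NNI counterpart edge (classes b/c have a natural
  counterpart) or the 0.1 substitutions/site default. Optimizing every new
  edge is available via `sdagConfig(optimizeAllNewEdges = TRUE)`.
* **GP initial refinement.** Whether the optional global branch-length
  refinement at initialization optimizes a per-edge or whole-graph GP
  objective is unspecified; the package sweeps the per-edge objective over
  all edges and leaves the option off by default.
* **Leaf nodes as subsplits.** Leaves are degenerate subsplits (empty
  clade + singleton); any alternative representation is isomorphic.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `brlenLower`, `brlenUpper` | 1e-6, 10 | Brent bounds, substitutions/site |
| `brlenTol` | 1e-4 | absolute convergence tolerance per sweep |
| `maxSweeps` | 5 | coordinate-ascent sweeps |
| `newEdgeInit` | 0.1 | initial length for edges with no counterpart |
| `enumerationCap` | 1e5 | guard on brute-force enumerations |
| `optimizeAllNewEdges` | FALSE | top pruning: optimize non-central new edges |

Branch-length optimization is coordinate ascent: one length at a time with
Brent's method, sweeping until the largest change falls below `brlenTol` or
`maxSweeps` is reached; the incumbent is kept whenever a line search fails
to improve it, so the objective never decreases between sweeps.

## Numerical choices

PLVs are rescaled per node and per site so the maximum entry is 1, with the
log factors accumulated separately; sums over parallel subtree choices with
unequal scale factors are aligned to the larger factor before adding. Sites
with identical columns are pattern-compressed once and shared by the
single-tree and sDAG likelihoods. Branch lengths written to Newick carry 10
significant digits (lossless at the tested tolerances); sDAG serialization
uses 17. Completion-added edges carry an NA sentinel length and every
likelihood path refuses to touch a sentinel, so a missing length assignment
is an error rather than a silent zero. Zero-length conflicts (impossible
site columns) produce `-Inf` log likelihood rather than an error.

## What the synthetic data emulate — and what they do not

`randomRootedTopology()` draws uniformly over rooted bifurcating labeled
topologies by sequential attachment (taxon *k+1* attaches at any of the
*2k−1* positions), with branch lengths Exponential with mean 0.1
substitutions/site — a typical scale for the alignments this kind of method
is benchmarked on. `simulateJCAlignment()` evolves i.i.d. uniform root
states down the tree under the same Jukes-Cantor model the likelihood
assumes. The generator therefore exercises the algorithms under their own
model: passing tests demonstrate correctness of the machinery (DP versus
enumeration, search recovery at a few hundred sites), not robustness to
model misspecification. Real alignments bring rate variation, base
composition bias, indels and alignment error, none of which are simulated;
conclusions about posterior coverage on real data require real empirical
posteriors.

Correctness checks run at deliberately small scale — four to seven taxa, a
handful of trees, up to a few hundred sites, and enumeration oracles capped
at 1e5 topologies — chosen so each property is verifiable against exhaustive
computation.

## Known limitations

* Jukes-Cantor only; the likelihood layer is structured so a fixed GTR
  matrix could replace the transition function, but none is exposed.
* Rooted topologies only: no unrooted splits, no rootings-union
  construction, and the posterior-table reader rejects non-bifurcating
  root degrees.
* The searches favor correctness over the constant-time PLV reuse a
  production C++ implementation would use; they are intended for the small
  instances where their behavior can be verified, and scale roughly
  quadratically in sDAG size.
* Credible-set evaluation takes an empirical topology posterior as input;
  the package does not run MCMC.
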