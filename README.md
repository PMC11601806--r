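# sdagsearch

Systematic search for high posterior density phylogenies with subsplit DAGs.

## The problem

Bayesian phylogenetic inference wants a posterior distribution over rooted
tree topologies, but the credible region is a vanishing fraction of a
super-exponential space, and MCMC explores it by a random walk whose larger
moves are mostly rejected. `sdagsearch` takes a systematic route instead: it
represents a whole *collection* of rooted bifurcating topologies in one
**subsplit directed acyclic graph (sDAG)** and enlarges that structure
greedily with **nearest-neighbor-interchange (NNI)** operations, aiming for a
small sDAG whose topology set carries most of the posterior density. The
package is aimed at methods researchers in Bayesian phylogenetics who want a
fully tested, desk-scale reference implementation of the data structures and
both search criteria.

## The core objects and criteria

A *subsplit* is an ordered pair of disjoint clades `{W, Z}` labeling an
internal node with the bipartition of the taxa below it; sDAG edges
`(t, clade) -> s` connect a parent subsplit to a child partitioning one of
its clades, and each edge carries one branch length, so topologies in the
sDAG correspond one-to-one to trees. An NNI on an sDAG edge with
`t = {X∪Y, Z}`, `s = {X, Y}` *adds* subsplits `t' = {X∪Z, Y}`,
`s' = {X, Z}` and a small set of induced edges, never removing anything; the
new edge `t' -> s'` is the NNI's *central edge*.

Candidate NNIs are ranked by one of two likelihoods (Jukes-Cantor model,
fixed per-edge branch lengths `ψ`, alignment `Y` with sites `Y_j`):

* **top pruning** — the classical Felsenstein likelihood
  `p_ψ(Y | τ_bk)` of the *best known tree* `τ_bk` for the central edge,
  a tree assembled deterministically from per-edge *choice maps* that
  approximates `max_{τ ∈ T_e} ∏_j p_ψ(Y_j | τ)`;
* **generalized pruning (GP)** — the per-edge topology-marginal composite
  likelihood `∏_j Σ_{τ ∈ T_e} p_ψ(Y_j | τ) p(τ | e)` over the set `T_e` of
  trees through the central edge (uniform `p(τ|e) = 1/|T_e|`), computed by a
  shared-PLV dynamic program that scales with sDAG size, not `|T_e|`.

The package also provides sDAG probability distributions (per-clade edge
probability vectors, topology probabilities, frequency-count fitting,
sampling), credible-set and posterior-coverage evaluation, Newick and
alignment I/O, and seed-driven fixture generators (uniform random rooted
topologies, JC sequence simulation).

## A worked example

Two seven-taxon topologies merge into an sDAG that contains four topologies
(the union has two root-split options and two resolutions of the clade
`{4,5,6}`):

```r
library(sdagsearch)
taxa <- as.character(0:6)
tau1 <- parseNewick("(0,(1,(2,(3,(4,(5,6))))));", taxa)
tau2 <- parseNewick("((0,1),(2,(3,((4,6),5))));", taxa)
d <- sdagFromTopologies(list(tau1, tau2), taxa)
d
#> SubsplitDAG on 7 taxa: 18 nodes, 23 edges, 4 topologies
```

Give the root split `{{0,1},{2,...,6}}` probability 0.4 and the resolution
`{{4},{5,6}}` probability 0.3; the topology containing both then has
probability `0.4 × 0.3`:

```r
rho <- paste0(strrep("0", 7), "|", strrep("1", 7))
pr <- list()
pr[[paste(rho, "right")]] <- setNames(c(0.4, 0.6), c(
  paste(rho, "right", "1100000|0011111"),
  paste(rho, "right", "1000000|0111111")))
pr[[paste("0001000|0000111", "right")]] <- setNames(c(0.3, 0.7), c(
  paste("0001000|0000111", "right", "0000100|0000011"),
  paste("0001000|0000111", "right", "0000101|0000010")))
probs <- edgeProbabilities(d, pr)
topologyProbability(d, probs, parseNewick("((0,1),(2,(3,(4,(5,6)))));", taxa))
#> [1] 0.12
```

A small top-pruning search on simulated data, started from a deliberately
wrong caterpillar topology, walks back to the generating tree:

```r
gen <- parseNewick("((0:0.1,1:0.15):0.08,(2:0.12,3:0.2):0.09);", as.character(0:3))
aln <- simulateJCAlignment(gen, 600, seed = 7)
start <- parseNewick("(((0:0.1,1:0.1):0.1,2:0.1):0.1,3:0.1);", as.character(0:3))
res <- tpSearch(list(start), aln, maxIterations = 5)
res$trace
#>   iteration                   central  tpLogLik nNodes nEdges nTopologies
#> 1         1 1100|0011 right 0010|0001 -2272.844     10     12           2
#> 2         2  1011|0100 left 1000|0011 -2265.635     12     17           3
#> 3         3 1000|0111 right 0100|0011 -2267.020     14     22           4
#> 4         4  1101|0010 left 1100|0001 -2283.807     16     27           5
#> 5         5  0101|0010 left 0100|0001 -2375.127     18     32           6
containsTopology(res$sdag, gen)
#> [1] TRUE
```

Each trace row is one accepted NNI: its central edge (subsplits as
membership bitstrings over the taxon order), the cached top-pruning log
likelihood at insertion time, and the growing sDAG's node/edge/topology
counts. `gpSearch()` has the same interface under the GP criterion, and the
`sdagsearch` script in `exec/` exposes `simulate`, `build-sdag`,
`tp-search`, `gp-search` and `evaluate` subcommands for shell use.

## Learning more

The methods vignette (`vignettes/sdag-methods.Rmd`) documents the model and
both criteria in detail, the numerical choices (PLV scaling, Brent bounds,
pattern compression, sentinel branch lengths), the design decisions taken
where the underlying algorithm descriptions were open, and what the
synthetic-data generators do and do not emulate.
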