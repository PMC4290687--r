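---
title: "Hub ranking methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub ranking methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubrank)
```

## Scope and model

`hubrank` ranks the nodes of a simple undirected graph — typically a
protein–protein interaction (PPI) network — by eleven topological scores,
and evaluates how well each score predicts a binary node label (essential /
non-essential). The graph model is deliberately minimal: opaque,
case-sensitive string node IDs; no edge weights, directions, self-loops or
parallel edges. Loaders drop self-loops and collapse duplicate or reciprocal
records, and keep nodes declared without edges as degree-0 vertices, since
real interaction exports routinely contain all three.

Every score is a function `F(v)` of the graph alone. A node `u` outranks `v`
when `F(u) > F(v)`; exact ties are broken by node ID (byte order) so that
rankings, and everything downstream of them, are reproducible across
machines and locales.

## The four local scores

Local scores depend only on the open neighbourhood `N(v)`.

* **Degree** counts neighbours.
* **MNC** induces the subgraph on `N(v)` and reports the vertex count of its
  largest connected component `MC(v)`.
* **DMNC** reports `|E(MC(v))| / |V(MC(v))|^ε`. The exponent `ε` (default
  1.7, argument `epsilon`) interpolates between edge counting (`ε = 0`) and
  strong punishment of large sparse neighbourhoods; values near 1.7 favour
  dense medium-sized complexes over star centres, which is what makes DMNC
  find low-degree essential proteins that degree-like scores miss.
* **MCC** sums `(|C| − 1)!` over all maximal cliques containing `v`. The
  factorial rewards membership in large protein-complex-like cliques
  super-exponentially; a node whose neighbourhood is edgeless only has its
  incident edges as maximal cliques, so its MCC equals its degree.

Degenerate input: an isolated node has no neighbourhood, and all four local
scores define it as 0. For MCC this is a deliberate choice — the clique set
excludes singleton "cliques", because summing `0! = 1` over them would give
an isolated node a *higher* score than the degree-fallback reading implies.

Maximal cliques are enumerated through igraph's Bron–Kerbosch implementation
(pivoting + degeneracy ordering); the package's contract is only that every
maximal clique of size ≥ 2 appears exactly once, which the test suite checks
against an exhaustive subset oracle. Clique enumeration is exponential in
the worst case; dense graphs beyond a few thousand nodes can be slow, and
factorials overflow double precision to `Inf` past clique size 170 (exact up
to size 18) — far beyond any biologically plausible complex.

When several neighbourhood components tie for `MC(v)`, the one whose sorted
vertex list is lexicographically smallest is used. MNC never notices (size
is tied), but DMNC can, when tied components have different edge counts; a
deterministic pick was preferred over an unspecifiable fidelity to the
original plugin's internal order.

## The seven global scores and disconnected networks

Hop distances `dist(u, v)` are infinite across components, which breaks the
classic definitions on disconnected graphs. The package computes
shortest-path machinery per component and rescales, where needed, by the
component fraction `|V(C(v))| / |V|`; on a connected network the factor is 1
and the classic scores are recovered (a property the test suite asserts).

* **Closeness** uses the reciprocal-sum form `Σ 1/dist(v, w)`, so
  unreachable pairs contribute 0 with no special casing.
* **EcCentricity** is the component fraction times the inverse eccentricity
  of `v` (maximum distance from `v` within its component).
* **Radiality** is the component fraction times
  `Σ_w (Δ + 1 − dist(v, w))`, `Δ` the component diameter, divided by the
  *per-node* maximum distance `max_w dist(v, w)`. A second normalisation
  (`normalization = "size"`) divides by `|V(C(v))| − 1` instead, the textbook
  convention. The two are **not** rank-equivalent even within one component —
  the default divides by a quantity that varies from node to node — so the
  choice is exposed as an argument rather than hidden; the default follows
  the formula layout the plugin's description prints. The exact relation
  `Rad_size(v) = Rad_ecc(v) · ecc(v) / (|C| − 1)` is regression-tested.
* **BottleNeck** builds one BFS shortest-path tree per root. A node's
  subtree size (nodes whose root-path passes through it, itself included;
  the whole tree for the root) is compared against a quarter of the tree:
  strictly exceeding it earns one point from that root. Because the tree is
  not unique, parents are fixed deterministically — the smallest-ID
  neighbour at the previous BFS depth — and the BFS frontier is processed in
  sorted order. This makes BottleNeck reproducible but *ID-dependent*:
  relabelling nodes can change exact scores wherever parents were tied,
  which is why the isomorphism-invariance tests cover the other
  shortest-path scores but not BottleNeck.
* **Stress** and **Betweenness** sum `σ_st(v)` and `σ_st(v)/σ_st` over
  unordered within-component pairs `{s, t}` with `s, t ≠ v` — the classic
  Freeman/Brandes convention. Summing ordered pairs would exactly double
  every score and leave all rankings unchanged.
* **EPC** draws, in each of `iterations` rounds (default 1000), one uniform
  `[0, 1)` number per edge and deletes edges whose number falls below
  `threshold`; the score is the average number of nodes still connected to
  `v` (itself included), divided by `|V|`. The score therefore scales
  linearly with `iterations` — the printed formula is kept as is, since
  rankings are scale-invariant. The threshold has no canonical value in the
  method's description; 0.5 is the default and both it and the iteration
  count are arguments and CLI flags. Edge numbers are drawn in a fixed
  order (edges sorted by endpoint IDs), so one seed gives bit-identical
  scores across platforms; `[0, 1)` half-open draws are what `runif()`
  provides.

Isolated nodes score 0 under Closeness, EcCentricity and Radiality (their
sums and maxima range over empty sets); under BottleNeck they keep the one
point from their own singleton tree, and under EPC they keep the
self-connectivity term, so `EPC(v) ≥ iterations / |V|` always.

## Ranking, top-k and subnetwork extraction

`rank_nodes()` orders by score descending with ID tie-breaks and adds a
`normalized_rank` in `[0, 1]` (1 = best), the numeric stand-in for a
red-to-green essentiality colour ramp. `top_k()` cuts strictly at `k` by
default; since the behaviour of a "top group" at a tied boundary is
genuinely ambiguous, `include_ties = TRUE` extends through the tie instead.
`expand_first_stage()` adds all direct interactors of a selection;
`group_shortest_paths()` joins non-adjacent same-component pairs with
abstract "dotted" edges carrying the hop distance and one concrete shortest
path (the lexicographically smallest node sequence from the smaller-ID
endpoint — again a determinism-over-arbitrariness choice). Cross-component
pairs are simply omitted. Re-scoring an extracted subnetwork is a supported
workflow: views are plain networks plus edge tables.

## The benchmark

`degree_threshold()` returns the largest integer `t` such that nodes of
degree `> t` still hold more than half of the total degree; the partition
into high-/low-degree classes uses strict `>`. Precision@k is the essential
fraction of the top `k`; the overlap matrix reports
`100 · |top_k(A) ∩ top_k(B)| / k` for every method pair; the low-degree
table counts, per method and cut-off, the low-degree nodes in the top `k`
and how many of those are essential. Essential labels are plain one-ID-per-
line files; multiple files are unioned, an optional two-column TSV remaps
IDs first, and labels absent from the network are dropped with a warning —
the package documents this as its own rule and does not claim to reproduce
any particular external dataset's label bookkeeping.

## The synthetic fixture generator

`generate_fixture()` emulates the one structural fact the local methods
exploit: essential proteins cluster into dense complexes. It plants
vertex-disjoint cliques (default three 6-cliques) on top of a sparse
Erdős–Rényi background (default 200 nodes, pair probability 0.02, matching
a sparse interaction map's density), wires clique–background pairs with the
same probability, and labels clique members essential with probability 0.9
and background nodes with probability 0.05 (independent Bernoulli draws).
No extra edges are added between different planted cliques, so each planted
clique is maximal by construction.

What the fixture does *not* emulate: scale-free degree distributions,
date/party hub structure, overlapping complexes, false-positive edge noise
correlated with degree, and the sheer size of real interactomes. Passing
the recovery tests therefore shows that the scores implement their
definitions and that MCC-style clique scoring recovers planted modular
structure; it does not by itself certify performance on real PPI data,
where the headline comparisons require the original external network and
label sets.

## Numerical and testing choices

Problem sizes in the test suite were chosen so brute-force oracles stay
exact and fast: exhaustive-subset clique oracles up to n = 12, neighbourhood
component oracles to n = 20, Floyd–Warshall / explicit path-enumeration
oracles to n = 40 (50 random graphs, sparse enough that disconnected cases
occur naturally), 100-graph property sweeps at n ≤ 16, and a fixed 100-node
clique-planted graph for EPC rank-stability across seeds. The EPC stability
check sits deliberately in the sub-critical percolation regime (mean degree
≈ 3 at threshold 0.5): there, node scores are dominated by structure and
ranks are stable; in dense regimes the percolated graph stays one giant
component and rank order degenerates into Monte-Carlo noise.

Real scores are compared at tolerance 1e-9; integer-valued scores exactly.
All randomness — fixtures, percolation, test graphs — flows through
explicit seeds, and seeded helpers snapshot and restore the caller's RNG
state so library code never perturbs a user's random stream.

## Known limitations

* Pure-R BFS machinery targets desk-scale networks (thousands of nodes);
  interactome-scale all-pairs work is possible but slow.
* Weighted or directed networks are out of scope, as are identifier
  translation services beyond the generic two-column remap.
* BottleNeck scores depend on the deterministic tree tie-break (see above);
  alternative readings of "paths meeting at a node" (≥ instead of >, or
  excluding the root) would shift scores by small amounts.
* EPC's threshold semantics at the interval endpoints follow `runif()`'s
  half-open `[0, 1)`: threshold 0 keeps every edge, threshold 1 removes
  every edge.

```{r example}
fx <- generate_fixture(seed = 1)
scores <- hub_score(fx$network, methods = c("Degree", "MCC"), epc_seed = 1)
head(rank_nodes(scores, "MCC"), 3)
```
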