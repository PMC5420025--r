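---
title: "Level-1 networks, their triplet and cluster systems, and when they determine the network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-1 networks, their triplet and cluster systems, and when they determine the network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1net)
```

## The model

A binary level-1 network on a taxon set $X$ ($n = |X| \ge 2$) is a rooted
directed acyclic graph without loops or parallel arcs whose sinks are
bijectively labelled by $X$, whose root has in-degree 0 and out-degree 2, and
whose other interior vertices are either split vertices (in-degree 1,
out-degree 2) or hybrid vertices (in-degree 2, out-degree 1); every biconnected
component of the underlying undirected graph contains at most one hybrid
vertex. Under these degree constraints each non-trivial biconnected component
is an undirected cycle — a *gall* — formed by two directed paths from a gall
root down to its hybrid vertex. We follow the standing convention that every
underlying cycle has at least 4 vertices: a 3-cycle is indistinguishable from a
split vertex from the point of view of the triplets and clusters the network
induces, so admitting it would only create spurious non-uniqueness.
`build_network()` enforces all of this and reports every violated invariant at
once.

Equivalence of networks is graph isomorphism that is the identity on the taxa.
Internal vertex identifiers are opaque bookkeeping and never carry meaning.

Derived structure:

* a *cut arc* is an arc whose deletion disconnects the underlying graph
  (detected by bridge search); it is *trivial* when its head is a leaf and
  *highest* when no cut arc lies on a directed path above it. $c_N$ counts the
  non-trivial cut arcs.
* the *Cut partition* of $X$ collects the clusters below the heads of the
  highest cut arcs. For the triplet system induced by a level-1 network it
  coincides with the maximal non-trivial SN-sets, which `maximal_sn_sets()`
  computes independently by exhaustive subset search; the tests cross-check
  the two routes exhaustively at 4 taxa.
* property flags: *proper* (at least one gall), *simple* (one gall, every leaf
  adjacent to its cycle), *4-outwards* (no underlying cycle with at most 4
  vertices), *saturated* (no vertex incident with more than one cut arc). We
  read "saturated" literally: a tree root is incident with two cut arcs, so no
  tree — and no network with an interior tree vertex — is saturated. Leaves are
  unproblematic (one trivial cut arc each).

## Canonical form and equivalence

`canonical_form()` encodes a network bottom-up: a leaf by its taxon, a split
vertex by the sorted pair of its child encodings, and a gall by the
lexicographic minimum over its two side orientations of the triple (left side
subtree encodings top-to-bottom, right side encodings, hybrid subtree
encoding). In a binary level-1 network the blob decomposition is unique and the
reflection of a gall is its only symmetry, so equal encodings characterize
equivalence. Rather than trusting that argument, the test suite compares the
encoding against an independent VF2 labelled-isomorphism oracle (igraph, leaf
labels as vertex colours) on *all* pairs of enumerated networks up to 4 taxa
and on random pairs at 5 taxa. Taxon names may not contain the delimiter
characters `<>()[]|,;` used by the encoding; validation rejects them.

## Triplet systems: two algorithms

The triplet $ab|c$ is consistent with $N$ when $N$ contains distinct vertices
$v, w$ and directed paths $v \to c$, $v \to w$, $w \to a$, $w \to b$ that
pairwise share no vertex beyond the common endpoints $v$ and $w$ — i.e. when
$N$ contains a subdivision of the triplet. `triplet_system(N, "paths")`
implements this definition directly: for each candidate triplet it scans the
(few) ancestor pairs $(v, w)$ that pass a reachability pre-filter and
enumerates all directed paths between the relevant endpoints, which is cheap in
a level-1 network because at most two paths exist per gall traversed.
`triplet_system(N, "trees")` instead takes the union of the triplet systems of
all displayed trees (one per choice of hybrid in-arc per gall, $2^{g(N)}$
switchings, deduplicated up to equivalence). For level-1 networks the two
notions agree; the suite asserts bit-for-bit equality on every enumerated
network up to 5 taxa and on random networks at 8 taxa, so each algorithm serves
as the oracle for the other. The displayed-tree route is the default because it
is faster.

## Restriction, Collapse

`restrict_network(N, X')` deletes the leaves outside $X'$ and then applies five
clean-up operations until none applies: (1) suppress in/out-degree-1 vertices,
(2) delete unlabelled sinks, (3) collapse parallel arcs, (4) if a gall is left
with exactly two outgoing cut arcs, delete its arcs and both cut arcs and hang
the two heads below the gall root, (5) delete sources of out-degree 1. The
engine operates on a multigraph because rule 1 can transiently create parallel
arcs. The rules are confluent up to equivalence; since that is asserted rather
than proved here, `order = "random"` applies applicable rule instances in
random order, and the property tests check that dozens of random `(N, X')`
pairs give the same canonical form under different schedules. Restriction to a
single taxon yields a degenerate one-leaf network; it is flagged by its empty
arc set and excluded from the theorem-verification universes, which start at 2
leaves.

`collapse_network(N)` replaces, for each highest cut arc, the whole
sub-network below it by one representative leaf. The representative is the
lexicographically least taxon of its block — any element would do
mathematically, but a deterministic choice makes results reproducible. The
result is always a simple network or a 2-leaf tree; the projected triplet
system (`collapsed_triplet_system()`, defined only when the Cut partition has
at least 3 blocks) equals the induced system of the collapsed network, which
the tests verify on the exhaustive 4-taxon universe.

## Defining systems for simple networks

For a simple network the cycle is labelled $v_1$ (hybrid), $v_2, \dots,
v_{n+1}$ with leaves $x_1$ (hybrid leaf) and $x_2, \dots, x_n$; the root sits
at position $i$. Both traversal orientations are legal; we fix the one whose
first side carries at least as many leaves as the second ($i - 2 \ge n - i +
1$), breaking ties by the lexicographically smaller bottom-to-top leaf
sequence. The orientation only has to be deterministic: the constructions
below are verified semantically, not against a fixed reference labelling.

* `defining_triplets_simple()` recursively removes $x_n$, restricts, and adds
  two triplets chosen by whether the root is adjacent to the hybrid
  ($i = n+1$), one step away ($i = n$), or further; the base case at $n = 4$
  is the full 7-triplet system. The result has at most $2n - 1$ triplets.
* `defining_clusters_simple()` emits at most $n$ softwired clusters from one
  of three case formulas (nested cycle-cluster chains plus two or three small
  clusters anchoring the hybrid leaf), again selected by the root's position.

Uniqueness claims are always relative to an explicitly supplied universe:
`is_l1_defined_by_triplets(N, R, U)` asks whether every member of `U` whose
system contains `R` is equivalent to `N`. With an exhaustive universe this
realizes the class of all level-1 networks on $X$ computationally. The
acceptance suite verifies, for every one of the 300 simple networks on 5 taxa,
that both constructions define their network within the exhaustive universe of
2880 networks, and that every saturated 4-outwards member is defined by its
full triplet and cluster systems — while non-saturated 4-outwards members with
strictly containing non-equivalent partners exist for both system types
(`search_containment_counterexamples()`).

`min_defining_triplets()` searches subsets of $R(N)$ breadth-first by size; it
is exponential and therefore guarded to 5 taxa, as is SN-set enumeration at 12
taxa and exhaustive enumeration at 6.

## Enumeration and the random generator

`enumerate_level1()` generates networks through the recursive blob
decomposition: a block is a leaf, a root split over an unordered bipartition,
or a root gall given by ordered side block lists and a hybrid block (at least
3 blocks, cycle length at least 4 — sides may be empty, which places the root
adjacent to the hybrid). Reflection duplicates are removed after generation by
the canonical encoding rather than by symmetry-breaking during generation;
that is simpler and verified correct by the VF2 oracle at small $n$. The
resulting universe sizes (12 networks on 3 taxa, 153 on 4, 2880 on 5, of which
3/15/105 are trees and 9/48/300 simple) are recorded but not asserted against
any external value; the tree counts are cross-checked against phangorn's
independent rooted-tree generator, and `enumerate_simple()` provides a second,
direct construction of the simple subclass that must agree with the filtered
universe.

`random_level1()` draws a shape top-down: with probability `gall_rate`
(default 0.4, chosen so that networks with several galls are common at 10
taxa without degenerating into a single giant cycle) the current block becomes
a gall whose block sizes are drawn uniformly over admissible compositions —
an arbitrary but documented choice, with no distributional claim attached;
otherwise a random split. It is seeded and restores the caller's RNG state.
These generated networks are *exact* members of the model class, so passing
tests certify the combinatorial machinery, not robustness to noisy or
non-level-1 input: real data yield triplet/cluster estimates with errors, and
nothing here addresses reconstruction from such estimates (out of scope, as is
any level-$k \ge 2$ support, non-binary vertices or branch lengths).

## Problem sizes and numerical choices

The test and verification workloads run exhaustively at 3–5 taxa (the smallest
sizes at which every phenomenon of interest — including the containment
counterexamples — already occurs) and use 100 seeded random networks at 10
taxa for the counting formulas; these sizes keep the full suite in the
minutes range on one CPU. There is no floating-point content anywhere: all
quantities are exact set and graph computations, so no tolerances are
involved. Determinism comes from sorted serializations, the canonical form,
and explicit seeds; the CLI refuses hidden entropy by requiring `--seed` only
where randomness exists (the exhaustive subcommands have none).

## Known limitations

* Exhaustive enumeration at 6 taxa is possible (guarded) but slow in plain R;
  beyond 6 the combinatorics explode and only the random generator remains.
* The path-based consistency check and SN-set enumeration are exponential by
  design (desk-scale verification tools), hence the guards noted above.
* A search utility (`find_networks_with_softwired()`) is provided to locate
  networks realizing a given softwired system exactly, because a cluster
  system alone does not identify a drawing; it reports matches rather than
  assuming any particular topology.
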