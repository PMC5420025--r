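# l1net — combinatorics of binary level-1 phylogenetic networks

Phylogenetic networks generalize phylogenetic trees to evolutionary histories
with reticulate events such as hybridization or recombination. The
combinatorially simplest non-trivial class is the **binary level-1 (galled)
network**: a rooted DAG whose sinks are labelled by taxa, whose interior
vertices are split vertices (in/out degree 1/2) or hybrid vertices (2/1), and
whose underlying undirected cycles are vertex-disjoint — each biconnected
component contains at most one hybrid vertex. A non-trivial biconnected
component with its arc directions restored is a **gall**: two directed paths
from a gall root down to a hybrid vertex.

Two set systems are commonly used to reconstruct such networks from data:

* the **induced triplet system** `R(N)`: all rooted triplets `ab|c` for which
  `N` contains internally disjoint directed paths `v→c`, `v→w`, `w→a`, `w→b`;
* the **softwired cluster system** `S(N)`: the union of the hardwired cluster
  systems (leaf sets below each vertex) of all trees displayed by `N`.

A reconstruction method that returns *some* network consistent with the
observed triplets or clusters is only trustworthy if the generating network is
the *unique* one consistent with them. `l1net` provides the machinery to study
this question computationally:

* network validation, galls, cut arcs, the **Cut partition** (clusters below
  the highest cut arcs, equal to the maximal non-trivial SN-sets of `R(N)`),
  restriction `N|X'`, **Collapse**, displayed trees, and a canonical form that
  decides equivalence (leaf-label-preserving isomorphism);
* triplet systems by two independent algorithms (disjoint-path search and
  displayed-tree union), SN-set enumeration, hardwired/softwired clusters and
  cluster compatibility;
* counting results, verified exhaustively: a proper level-1 network on `n`
  leaves has `2n+1 ≤ |V| ≤ 3n−2` vertices and `2n+1 ≤ |A| ≤ 3.5(n−1)` arcs;
  the number of galls satisfies `g(N) ≤ n − c_N − 2` (with `c_N` the number of
  non-trivial cut arcs), tight for trees and for networks all of whose galls
  have three outgoing arcs; and `|S(N)⁻| = 3n − 4 − c_N`;
* **uniqueness ("L1(X)-definedness") checks**: a network `N` is defined by a
  triplet system `R ⊆ R(N)` (cluster system `S ⊆ S(N)`) if, up to equivalence,
  `N` is the unique level-1 network on its taxa with `R ⊆ R(N')`
  (`S ⊆ S(N')`). The package constructs defining systems of size `≤ 2n−1`
  (triplets) and `≤ n` (clusters) for simple networks, verifies that every
  saturated, 4-outwards network is defined by its full induced systems, and
  searches exhaustive universes for containment counterexamples showing that
  4-outwards alone is not enough;
* exhaustive enumeration of all level-1 networks on up to 6 taxa, a seeded
  random generator, and extended-Newick / JSON / TSV I/O plus a small CLI.

Terminology: a network is *proper* if it has at least one gall, *simple* if it
has exactly one gall and every leaf hangs off its cycle, *saturated* if no
vertex is incident with more than one cut arc, and *4-outwards* if no
underlying cycle has 4 or fewer vertices.

## A worked example

The simple network on five taxa whose gall sides carry `x1, x2` and `x5, x4`
with hybrid leaf `x3`:

```r
library(l1net)
N <- parse_enewick("((x1,(x2,(x3)#H1)),(x5,(x4,#H1)));")
N
#> <l1net> binary level-1 network on 5 taxa: 11 vertices, 11 arcs, 1 gall(s), 0 non-trivial cut arc(s)
#>   taxa: x1, x2, x3, x4, x5
#>   ((x1,(x2,(x3)#H1)),(x5,(x4,#H1)));
```

A simple network has `|V| = |A| = 2n + 1` (here 11) and no non-trivial cut
arcs. Its induced triplet system has 16 elements — two triplets for six of the
ten 3-subsets, one for the rest:

```r
triplet_system(N)
#> <triplet system> 16 triplets on 5 taxa
#>   x1,x2|x3  x1,x2|x4  x1,x2|x5  x1,x3|x4  x1,x3|x5  x2,x3|x1  x2,x3|x4
#>   x2,x3|x5  x3,x4|x1  x3,x4|x2  x3,x4|x5  x3,x5|x1  x3,x5|x2  x4,x5|x1
#>   x4,x5|x2  x4,x5|x3

softwired_clusters(N, drop_full = TRUE)   # |S(N)^-| = 3n - 4 - c_N = 11
#> <cluster system> 11 clusters on 5 taxa
#>   {x1} {x1,x2} {x1,x2,x3} {x2} {x2,x3} {x3} {x3,x4} {x3,x4,x5} {x4} {x4,x5} {x5}
```

Not all 16 triplets are needed to pin the network down. The recursive
construction emits 9 = 2n − 1 of them, and checking against the exhaustive
universe of all 2880 level-1 networks on these taxa confirms that no other
network is consistent with all 9:

```r
D <- defining_triplets_simple(N)
D
#> <triplet system> 9 triplets on 5 taxa
#>   x1,x2|x3  x1,x2|x5  x1,x3|x5  x2,x3|x1  x2,x3|x5  x3,x4|x5  x3,x5|x1
#>   x3,x5|x2  x4,x5|x3

U <- enumerate_level1(5)
#> <l1 universe> 2880 pairwise non-equivalent networks on {x1,x2,x3,x4,x5} (filter: all)
is_l1_defined_by_triplets(N, D, U)$defined
#> [1] TRUE
```

The verification drivers run the counting formulas and uniqueness results over
a whole universe (`verify_counting(U)`, `verify_definedness(U)`) and
`search_containment_counterexamples(U, "triplet")` lists all non-equivalent
4-outwards pairs `(N', N)` with `R(N') ⊆ R(N)` — non-empty at five taxa, but
empty once both members are also required to be saturated.

A command-line front end for file-based workflows lives in `inst/cli/l1net.R`
(subcommands `validate`, `properties`, `triplets`, `clusters`, `cut`,
`collapse`, `restrict`, `define-triplets`, `define-clusters`, `enumerate`,
`verify`, `counterexamples`); see `?run_cli`.

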