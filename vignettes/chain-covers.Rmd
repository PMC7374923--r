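---
title: "Chain subgraph covers and the Lock/Key model of cytoplasmic incompatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain subgraph covers and the Lock/Key model of cytoplasmic incompatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaincover)
```

## The biological problem and its graph model

Cytoplasmic incompatibility (CI) is a reproductive manipulation exerted by
intracellular bacteria such as *Wolbachia*: a cross between an infected male
and a female that is uninfected, or carries a different strain, fails. A
crossing experiment over $n_1$ males and $n_2$ females is summarised by a
0/1 incompatibility matrix $C$ (rows = males, columns = females, $C[i,j]=1$
for an incompatible cross), equivalently by a bipartite graph $B(C)$ with
one edge per incompatible cross.

The quantitative Lock/Key model posits, for each toxin/antitoxin molecule
pair $l$, a Lock quantity $L[i,l]$ deposited in the sperm of male $i$ and a
Key quantity $K[j,l]$ in the eggs of female $j$; a cross succeeds exactly
when every Key quantity is at least the corresponding Lock quantity:

$$C[i,j] = 0 \iff K[j,l] \ge L[i,l] \ \text{for all } 1 \le l \le k.$$

A single molecule pair can explain $C$ exactly when $B(C)$ is a **chain
graph**: a bipartite graph with no induced $2K_2$ (two edges with disjoint
endpoints and no cross edge), equivalently one whose neighbourhoods on a
side are totally ordered by inclusion. In general, $k$ molecule pairs
suffice exactly when the edges of $B(C)$ can be covered by $k$ chain
subgraphs. The minimum number of Lock/Key pairs consistent with the data is
therefore the **minimum chain subgraph cover** size, an NP-hard quantity;
and because quite different covers can have the same size, the package also
enumerates *all* minimal covers rather than trusting a single optimum.

```{r fig2}
fig2 <- fig2_fixture()
fig2$matrix
minimum_cover_size(fig2$graph)
lockkey_from_cover(fig2$matrix, enumerate_minimal_covers(fig2$graph)[[1]])
```

## Enumerating maximal chain subgraphs

`enumerate_maximal_chain_subgraphs()` streams every inclusion-maximal
edge-induced chain subgraph exactly once, with polynomial delay between
solutions. The recursion rests on a structural fact: a chain subgraph $C$
whose largest neighbourhood sits at node $x$ is maximal iff (i) $N_C(x) =
N_G(x)$ is a *maximal neighbourhood* of the current graph (no other node's
neighbourhood strictly contains it) and (ii) $C \setminus E_G(x)$ is maximal
in the graph induced by $U \setminus \{x\}$ and $N_G(x)$. Each recursion
level therefore commits one *candidate* — one representative per maximal
neighbourhood, the smallest label among twins — restricts the female side to
its neighbourhood, and recurses until no edges remain.

Choices the procedure fixes (any fixed order is correct; these make output
byte-reproducible):

* candidates are visited in label order, depth-first, so the emission order
  is deterministic;
* twins are represented by the lexicographically smallest label;
* chains are emitted as `(male, female)` edge lists sorted lexicographically;
* `pivot_side` lets the recursion branch on the female side instead
  (`"auto"` picks the smaller side); the solution *set* is invariant.

Two combinatorial facts are exposed as testable properties: the number of
maximal chain subgraphs is at most $\min(|U|,|W|)!$ — each solution is
pinned down by one neighbourhood ordering of a side — and at most
$2^{\sqrt{m}\log_2 m}$. Both bounds are tight up to the extremal family
realised by `antimatching(n)`, the complete bipartite graph minus a perfect
matching, which has exactly $(n/2)!$ maximal chain subgraphs, one per
permutation of one side.

```{r antimatching}
length(enumerate_maximal_chain_subgraphs(antimatching(8)))  # 4! = 24
```

## Exact cover counting by inclusion–exclusion

Let $a(A)$ be the number of maximal chain subgraphs disjoint from an edge
set $A$. The number of ordered $k$-tuples (repetition allowed) of maximal
chain subgraphs whose union is the whole edge set is

$$c_k(G) = \sum_{A \subseteq E} (-1)^{|A|}\, a(A)^k,$$

and the minimum cover size is the smallest $k$ with $c_k(G) \ne 0$ (the
scan is guaranteed to stop at or before $k = |\mathscr{C}(G)|$, since the
set of all maximal chain subgraphs is itself a cover). The identity counts
*ordered* tuples — $a(A)^k$ factorises over $k$ independent choices — a
resolution the brute-force tuple-counting oracle in the test suite pins
down; the minimum-$k$ extraction is unaffected by the ordered/unordered
distinction.

Implementation notes:

* `count_avoiding()` follows the constructive route: enumerate the maximal
  chain subgraphs of $(U \cup W, E \setminus A)$ and keep those still
  maximal in $G$. This equals filtering $\mathscr{C}(G)$ by disjointness
  from $A$ (a property test asserts the agreement), which is how
  `count_covers()` obtains all $2^m$ values of $a(\cdot)$ at once: chains
  are encoded as edge bitmasks and a subset-sum (zeta) transform yields
  $a(A)$ for every $A$ in $O(2^m m)$ vector operations.
* Terms are grouped by distinct $a$-value, so the alternating sum reduces
  to $\sum_v s_v\, v^k$ over a handful of values, with $s_v$ an exact
  signed count.
* The grouped sum is evaluated in the package's exact big-integer
  arithmetic (`bigint`): already at desk scale $a(\emptyset)^k$ exceeds
  both 32-bit integers and the $2^{53}$ exact range of doubles, so no
  floating point enters this module.
* The $2^m$ scan is guarded at `max_edges = 20` by default (memory and time
  both scale as $2^m$); `force = TRUE` raises it to the hard cap of 25
  bits. The guard documents the exponential nature of the routine rather
  than hiding it.
* Edgeless graphs get minimum cover size 0 by convention (there is nothing
  to cover); $c_k = 0$ for every $k \ge 1$ there, so the scan special-cases
  $m = 0$.

`max_induced_matching()` provides the standard certified lower bound: edges
that pairwise form induced $2K_2$s must lie in pairwise distinct chains of
any cover. It is an exhaustive branch-and-bound maximum-clique search on
the edge-conflict graph, guarded like the counting routines.

## Enumerating all minimal covers: essential edges

For an edge $e$, the conflict set $\mathcal{M}_e$ holds every edge forming
an induced $2K_2$ with $e$, and $\mathscr{C}_e$ the maximal chain subgraphs
containing $e$. Containment reverses between the two families:
$\mathscr{C}_e \subseteq \mathscr{C}_{e'} \iff \mathcal{M}_e \supseteq
\mathcal{M}_{e'}$. An edge is **essential** when no other edge has a
strictly larger conflict set; edges with identical, inclusion-maximal
conflict sets are all essential (their chain families coincide). A maximal
chain subgraph belongs to some minimal cover exactly when it contains an
essential edge — and any family of maximal chains covering all essential
edges automatically covers every edge, because each non-essential edge is
contained in every chain that contains some essential edge dominating it.

`enumerate_minimal_covers()` therefore:

1. computes conflict sets (a direct four-node condition per edge pair) and
   the essential edges by pairwise strict-inclusion comparison of sorted
   conflict sets;
2. enumerates only the maximal chains containing an essential edge.
   The recursion is pruned on branches whose committed edges already
   intersect $\mathcal{M}_e$ for every essential $e$ (a maximal chain
   contains $e$ iff it avoids $\mathcal{M}_e$ entirely), with a final
   membership filter guaranteeing output correctness independently of the
   pruning;
3. builds the hypergraph whose vertices are the essential edges and whose
   hyperedges are those chains, and enumerates its minimal set covers;
4. re-validates each emitted cover against the *full* edge set (coverage
   and irredundancy). The theory implies this assertion can never fire; it
   is kept as a safety check that would surface a violation as an error
   rather than repairing it silently.

The minimal set-cover enumerator is an ordered include/exclude backtracking
with two safe prunes — an uncovered element no remaining set can reach
kills the branch, and so does a chosen set whose elements are all covered
by the other chosen sets (no extension of such a selection is minimal).
Every minimal cover is emitted exactly once; the known quasi-polynomial
worst-case bound for this problem is *not* claimed for this implementation,
whose contract is correctness.

## Lock/Key construction

`lockkey_from_chain()` turns one chain subgraph into one Lock/Key column by
degree-class grading: males with within-chain degree $r$ form class $B_r$
and receive Lock quantity $r$; a female first covered by class $r$ (the
smallest within-chain degree among her neighbours) receives Key quantity
$r-1$. Class indices follow the degrees exactly and may skip values when
classes are empty — no re-compaction — which reproduces the worked values
$L = (3, 1)$, $K = (0, 2, 2)$ of the two-male example. Two completions make
the column total:

* males absent from the chain get Lock 0 (absence of the molecule);
* females outside every class neighbourhood get Key $d$, the largest class
  index: enough keys for every lock of the column, the minimal-information
  completion that makes the explains relation hold globally.

The within-column *values* are conventional; only their relative order
matters, and a property test asserts that any strictly increasing remapping
of a column's joint value set preserves the explains relation.
`lockkey_from_cover()` stacks one column per chain and asserts
`explains()` before returning — a hard postcondition. `matrix_from_lockkey()`
reads the model generatively, and the round trip through any valid cover
reproduces the incompatibility matrix exactly.

## Interval orders

A bipartite (two-layer) poset is an interval order iff its comparability
graph is a chain graph, and its interval dimension equals the minimum
chain-cover size of the bipartite complement of that graph. The `posets`
layer is a thin facade over the cover machinery: `interval_dimension()`
computes exactly that, and `enumerate_interval_posets()` reads maximal
chain subgraphs of the comparability graph as maximal interval reductions,
and complements of maximal chain subgraphs of the bipartite complement as
minimal interval extensions. When the complement is edgeless the poset is
already an interval order and the dimension is reported as 1 — a documented
convention for the degenerate case (a realisable order needs at least one
extension), not a claim from the theory.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions for all randomised tests:

* `antimatching(n)` — the extremal family with $(n/2)!$ maximal chains,
  minimum cover 2 and maximum induced matching 2 for $n \ge 6$; exercised
  at $n \in \{4, 6, 8\}$.
* `random_bipartite(n1, n2, p, seed)` — independent edges with probability
  $p$. The oracle suites draw sides of 2–5 nodes and $p \in [0.25, 0.6]$,
  redrawing (deterministically, by advancing the derived seed) any instance
  with more than 12 edges or more than 14 maximal chains so the exhaustive
  $2^m$ and $2^{|\mathscr{C}|}$ oracles stay exact; this guards the oracle's
  feasibility, not the method under test, which runs unmodified on larger
  inputs.
* `planted_cover(n1, n2, k, seed)` — a union of $k$ random chain graphs
  (random nested prefixes of a permuted female side, non-decreasing sizes
  along a permuted male side), certifying minimum cover size $\le k$.

All generators are pure functions of their parameters and seed, and they
restore the caller's RNG state. What random instances do *not* emulate:
block structure of real crossing panels, missing or noisy entries (the
model here assumes complete, correct data), and the label semantics of
actual strains. Passing the oracle suites therefore certifies algorithmic
correctness on the model class, not robustness to experimental noise.

## Problem sizes, numerical choices, limitations

The test suite runs the full oracle battery — enumeration vs exhaustive
subset scan, inclusion–exclusion vs tuple counting for $k \le 3$,
conflict/chain-family containment on all edge pairs, minimal-cover stream
vs brute force — on 200 seeded random instances plus the named fixtures,
and completes in well under a minute; the acceptance script repeats a
60-instance summary. These sizes were chosen so every check is exact and
exhaustive.

Known limitations:

* the counting routines are exponential in $m$ by nature and guarded
  accordingly; the enumeration routines are exponential only in the output
  size;
* covers are built from *maximal* chain subgraphs (any cover can be
  coarsened to one such without increasing its size, so no generality is
  lost for minimisation or for minimal covers);
* weighted or probabilistic incompatibility, missing data, and non-bipartite
  structures are out of scope;
* the published *Culex pipiens* benchmark matrix is third-party data and is
  not shipped; the benchmark test and the CLI accept it as an ordinary CSV
  once the user obtains it (16 maximal chains, a minimum cover of 4, and a
  maximum induced matching of 4 are the expected outputs).
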