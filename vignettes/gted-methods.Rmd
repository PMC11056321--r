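---
title: "Computing the graph traversal edit distance: models, formulations, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing the graph traversal edit distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gted)
```

## The problem

A de Bruijn graph built from sequencing reads encodes a genome without
committing to one assembly: every Eulerian trail — a walk using each edge
exactly once — spells one candidate reconstruction. The **graph traversal
edit distance (GTED)** between two unidirectional, edge-labeled Eulerian
graphs $G_1, G_2$ is

$$\mathrm{GTED}(G_1,G_2) \;=\; \min_{t_1 \in \mathrm{trails}(G_1),\; t_2 \in
\mathrm{trails}(G_2)} \mathrm{edit}\big(\mathrm{str}(t_1),
\mathrm{str}(t_2)\big),$$

the edit distance between the two most similar strings the graphs can spell.
It allows genome graphs to be compared directly, without assembling them
first. *Unidirectional* means no two distinct nodes carry edges in both
directions (self-loops are fine); every input must be connected and admit an
Eulerian trail, either *closed* (all nodes balanced) or *open* (exactly one
source/sink imbalance pair). `validate_eulerian_unidirectional()` enforces
this contract and classifies the trail kind.

Computing GTED is NP-hard, so this package treats it as an exact
integer-programming problem at desk scale, together with a polynomially
sized relaxation-style lower bound that is interesting in its own right.

## The alignment graph

All formulations live on the **alignment graph** $\mathcal{A}(G_1,G_2)$
(`build_alignment_graph()`), the graph analogue of the string-alignment DP
matrix. Its vertices are pairs $V_1 \times V_2$; its edges are

* **vertical** $[(u_1,u_2),(v_1,u_2)]$ for $(u_1,v_1)\in E_1$: a character
  of $G_1$ aligned to a gap (cost `indel`),
* **horizontal** $[(u_1,u_2),(u_1,v_2)]$ for $(u_2,v_2)\in E_2$: a gap in
  $G_1$ (cost `indel`),
* **diagonal** $[(u_1,u_2),(v_1,v_2)]$: two characters aligned (cost
  `match` or `mismatch`).

Each edge *projects* to the input edge(s) it consumes (`project_path()`
lifts this to walks). A trail through the alignment graph whose projections
are Eulerian trails of both inputs is exactly an alignment of two spelled
strings, and its edge-cost total is the alignment cost.

To handle open and closed inputs uniformly, `augment_source_sink()` adds a
source $s$ and sink $t$ attached to every possible trail start/end
(open input: the full row/column of its imbalanced nodes; closed input: the
row and column of a deterministic anchor — the lexicographically smallest
node, a free choice that does not affect the optimum because the anchor row
and column are attached in full). These $\epsilon$ edges cost 0 by default
and project to nothing.

Repeats make edge multisets large, so edges are stored **merged** by
(head, tail, label) with integer multiplicities; alignment-edge variables
are then non-negative integers rather than binaries, and each input edge
$f$ must be covered exactly $M_i(f)$ times (its multiplicity). Merging by
(head, tail) alone would be wrong: edges with different labels price
diagonals differently and are covered by separate projection constraints.

## Three formulations

**Flow-projection lower bound** (`build_lower_bound_model()`,
`solve_ccted()`). Choose non-negative integer copy numbers $x_e$ minimizing
$\sum_e x_e\,\delta(e)$ subject to the projection constraints, unit
source/sink flow, and flow conservation at every product node. Nothing
forces the selection to be connected, so an optimum may decompose into
disjoint closed trails and the value is only a **lower bound** on GTED. On
closed inputs it equals the **closed-trail cover traversal edit distance
(CCTED)**: the minimum-cost matching between decompositions of each graph
into edge-disjoint closed trails, with a trail matched to the empty item
costing its length. `decode_cover_matching()` peels the selected subgraph
into trails and reports the matched pairs; peeling is deterministic
(smallest start node, smallest edge key first), and if the stripped s–t
component is open at the alignment level its two projections are still
closed trails, because all other peeled components are balanced and the
projection constraints balance the remainder.

**Iterative constraint generation** (`solve_gted_iterative()`). The exact
formulation adds, for every strongly connected subgraph $C$, the condition
"if all edges of $C$ are selected, some edge must leave $C$", linearized
with a binary $\beta_C$:
$\sum_{E(C)} x \ge |E(C)|\,\beta_C$,
$\sum_{E(C)} x - |E(C)| + 1 - W(C)\,\beta_C \le 0$, and
$\sum_{\varepsilon^+(C)} x \ge \beta_C$, where $W(C)$ bounds the selected
copies in $C$ by the larger of the projected multiplicity totals. These
constraints are exponential in number, so they are generated lazily: solve,
find strongly connected components of the selected subgraph that contain a
selected edge, do not contain $t$, and have no selected out-edge
(`find_violating_sccs()`), add their constraints — all components found in
an iteration at once, and constraints persist, being globally valid — and
re-solve. The objective sequence is non-decreasing and the loop terminates
because the family of generatable components is finite; a safety cap
(default 1000 iterations) returns the current valid bound with an explicit
non-optimal flag.

**Compact ordering formulation** (`build_compact_model()`,
`solve_gted_compact()`). In the style of Miller–Tucker–Zemlin tours, each
edge gets an integer order variable $d_e$ (sum of the step indices of its
selected copies) and a binary unused-indicator $y_e$: at every internal
node, outgoing order minus incoming order equals the number of selected
out-copies; the source edge has order 1 and the sink order equals the total
selection size. Summing the node constraints around any disconnected
component gives $0$ on the left and a positive count on the right, so only
single s–t trails are feasible and the optimum is exactly GTED.

*Big-M choice.* The indicator linearization needs constants with
$x_e + N y_e \ge 1$ and $d_e \le N^2 (1-y_e)$. We take $N$ to be the
**total** alignment-edge count including multiplicities: the merged row
count alone does not bound the order variables when multiplicities are
large (two self-loops of multiplicity 100 yield a handful of merged edges
but order sums in the thousands), while the multiplicity-expanded count
always does, since a trail has at most $N$ steps and each $d_e$ is a sum of
at most $x_e \le N$ step indices.

**Boundary-matrix (2-simplex) formulation** (`build_simplex_model()`).
Kept for cross-validation of the lower bound, not production: over the
*unmerged* alignment graph of two closed inputs, every pair of edge units
spans two oriented triangles; the boundary operator maps a triangle to
$+1$ on its two gap edges and $-1$ on its diagonal, and the feasible set is
$x = x^{\mathrm{init}} + [\partial]\,y$ with $y$ free integers and
$x^{\mathrm{init}}$ tracing one deterministic Eulerian trail of each input
along an anchor row/column. Adding boundary columns preserves both the
projection totals and flow conservation, and its optimum equals the
flow-projection bound on every closed fixture — an equality the test suite
asserts rather than assumes.

## Oracles

Because multiple non-trivial formulations must agree, the package carries
independent brute-force references (`levenshtein()` — also cross-checked
against `utils::adist` —, `cyclic_edit_distance()`,
`enumerate_eulerian_trails()`, `brute_force_gted()`,
`brute_force_ccted()`): exhaustive trail enumeration and cover/matching
enumeration on instances with up to ~6–8 edges per side, with an explicit
state limit (default $10^6$) that errors rather than truncating silently.
Strings of closed trails are compared **rotation-free** (minimum over
rotations of both strings): a closed trail fixes no start point, and a
closed trail in the alignment graph likewise fixes no rotation, so the
cover semantics force this choice. Open-trail strings are anchored.

## Solver backend

No formulation depends on a particular solver: models are declared against
a small container (`milp_problem()`) and solved by `solve_milp()`, which
runs the HiGHS solver through SciPy's `milp` interface in the system Python
(option `gted.python` / env var `GTED_PYTHON` select the interpreter).
HiGHS runs single-threaded here with a zero MIP gap, so optimal *values*
are reproducible; optimal *vertices* need not be unique, and downstream
code only ever relies on the value and on feasibility of the returned
assignment — decoding asserts, and tests verify, feasibility-level
properties rather than one particular optimum. Integrality is accepted at
tolerance $10^{-6}$ and integer variables are rounded before decoding.

## Instance generators

* `make_two_triangle_pair()`: the counterexample separating GTED from its
  lower bound — two 3-cycles sharing a node, spelling circular permutations
  of TTTGAA vs TTTAGA; exact distance 2, lower bound 0 via two disjoint
  zero-cost cycles.
* `make_ncycle_graph()`: a central cycle with peripheral cycles attached at
  nodes (or sharing a duplicated edge run), emulating segmental
  duplications and translocations; random ACGT labels under a seed.
* `make_hamiltonian_reduction()`: the Eulerian-closure construction behind
  the NP-hardness proof — vertex in/out splitting, a hub vertex, six edge
  families labeled over \{a, b, c\}, every antiparallel pair split through
  a dummy node into (x, \#) length-2 paths — plus the cycle graph spelling
  $q = \texttt{a\#}(\texttt{b\#a\#})^{n-1}(\texttt{c\#})^{2n-1}
  (\texttt{c\#b\#})^{m+1}$. The input digraph has a Hamiltonian path iff
  the distance between the two outputs is 0, which makes the pair a sharp
  end-to-end test of the exact solvers.
* `random_sequence_pair()` and `build_debruijn()`: uniform ACGT sequences
  with per-position substitutions at a chosen rate, turned into de Bruijn
  graphs (circular or linear; the published experiments do not say which,
  so both are provided).
* `random_eulerian_graph()`: rejection-sampled small closed graphs for
  property tests.

Generator defaults are the study conditions at desk scale: oracle
comparisons use closed graphs with at most 6 edges per side (20 seeded
pairs), and the difficulty-trend experiment uses pairs of 3-cycle graphs
with cycle lengths (3, 3, 4) — 10 edges per graph — grouped by the gap
between the exact distance and the lower bound. These sizes keep exhaustive
enumeration and repeated ILP solves tractable on one CPU while still
exercising every formulation; they do not probe numerical behaviour at
genome scale, where the published experience is that exact computation is
already impractical for a few thousand bases. What the synthetic families
deliberately do not model: sequencing errors, coverage-dependent
multiplicities, reverse complements, and alphabet sizes beyond \{A, C, G,
T\} — passing tests say nothing about those.

## Numerical and design notes

* Deterministic tie-breaks everywhere a choice is "arbitrary":
  lexicographic anchors, lexicographic edge keys in Hierholzer walks and
  trail peeling. This makes decoded artifacts reproducible without
  constraining the solver.
* The sink-side attachment when both inputs have open trails is oriented
  *into* $t$ (an edge from the pair of end nodes to $t$), keeping $t$ a
  true sink.
* A parallel $\epsilon$ source edge that the closed/closed augmentation
  would create twice at the anchor pair is de-duplicated; a duplicate can
  never help.
* Degenerate inputs: empty graphs are rejected; single-edge graphs, self
  loops, and multiplicity-only differences are all covered by tests.
* The lower-bound model also accepts open inputs (the augmentation makes
  the formulation uniform), but the cover interpretation is defined only
  for closed inputs; `solve_ccted()` flags this with `is_ccted`.
* `eps` cost defaults to 0; setting it positive prices trail endpoints and
  breaks the equality between decoded cover cost and objective, so the
  decoder does not assume it is zero — tests compare under the default.

## Limitations

Exact GTED is NP-hard and the iterative method's iteration count grows
quickly with the gap between GTED and its lower bound; the compact
formulation avoids iteration but carries big-M constants that weaken its
LP relaxation. Both are desk-scale tools. The package does not attempt
heuristic or approximate GTED, flow-based variants over string sets,
colored or bidirected de Bruijn graphs, or reverse-complement
canonicalization.
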