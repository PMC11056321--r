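# gted

Exact and lower-bound computation of the **graph traversal edit distance
(GTED)** between unidirectional, edge-labeled Eulerian graphs — the graph
class that de Bruijn assembly graphs live in. GTED compares two genome
graphs directly, without assembling them:

$$\mathrm{GTED}(G_1,G_2) = \min_{t_1 \in \mathrm{trails}(G_1),\, t_2 \in
\mathrm{trails}(G_2)} \mathrm{edit}(\mathrm{str}(t_1), \mathrm{str}(t_2)),$$

the edit distance between the most similar strings spelled by Eulerian
trails of the two graphs. The package is aimed at researchers studying
genome-graph comparison: it provides the alignment-graph construction, two
exact integer-linear-programming formulations, the flow-projection lower
bound and its interpretation as the closed-trail cover traversal edit
distance (CCTED), decoders for optimal solutions, brute-force oracles, and
deterministic benchmark-instance generators. Computing GTED is NP-hard, so
all exact computation is desk scale by design.

## What is implemented

| Function | Quantity |
|---|---|
| `solve_gted_compact()` | exact GTED, ordering-variable (MTZ-style) ILP |
| `solve_gted_iterative()` | exact GTED, lazy strongly-connected-component constraint generation |
| `solve_ccted()` | flow-projection lower bound; equals CCTED on closed inputs |
| `solve_simplex_lb()` | the same lower bound via the boundary-matrix (2-simplex) ILP |
| `decode_cover_matching()` / `extract_trail_and_alignment()` | matched closed-trail covers / the optimal alignment |
| `brute_force_gted()` / `brute_force_ccted()` | exhaustive references for small graphs |
| `build_debruijn()`, `read_graph_tsv()`, `read_fasta()` | input construction and I/O |
| `make_two_triangle_pair()`, `make_ncycle_graph()`, `make_hamiltonian_reduction()`, `random_sequence_pair()` | benchmark instance families |

Models are solved with the open-source HiGHS solver through SciPy's `milp`
interface in the system Python (configure with `options(gted.python =
...)` if needed).

## Worked example

The classic counterexample separating GTED from its lower bound: two
graphs, each two 3-cycles sharing a node, spelling circular permutations of
`TTTGAA` and `TTTAGA`.

```r
library(gted)
pair <- make_two_triangle_pair()

solve_gted_compact(pair$g1, pair$g2)$value
#> [1] 2

r <- solve_ccted(pair$g1, pair$g2)
r$value
#> [1] 0
decode_cover_matching(r$ag, r$solution)
#> cover_matching: 2 trail pair(s), total cost 0
#>   [GAA] ~ [GAA]  cost 0
#>   [TTT] ~ [TTT]  cost 0
```

The exact distance is 2 (two substitutions turn `TTTGAA` into `TTTAGA` in
the best rotation), but the lower-bound ILP attains 0: its optimum splits
into two disjoint cycles — `TTT` matched with `TTT` and `GAA` matched with
a rotation of `AGA` — a closed-trail cover matching rather than one trail.
That is exactly the CCTED value, and the decoded pairs show the matching.

The exact solvers also return the alignment itself:

```r
solve_gted_iterative(pair$g1, pair$g2)$trail
#> trail_solution: cost 2
#>   -GAATTT
#>   AGA-TTT
```

A command-line wrapper is included for shell use:

```sh
Rscript inst/cli/gted.R fixtures --family two-triangle --out-prefix /tmp/fx
Rscript inst/cli/gted.R compute --g1 /tmp/fx_g1.tsv --g2 /tmp/fx_g2.tsv \
    --method gted-compact --out /tmp/report.json
```

Graphs travel as TSV (`head<TAB>tail<TAB>label[<TAB>multiplicity]`), and
FASTA sequences can be turned into de Bruijn graphs with `build-graph
--k 4 --circular`.

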