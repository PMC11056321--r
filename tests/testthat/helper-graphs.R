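# small builders shared across test files

single_edge <- function(label, u = "u", v = "v") {
  labeled_graph(data.frame(head = u, tail = v, label = label))
}

triangle <- function(labels, nodes = c("a", "b", "c")) {
  labeled_graph(data.frame(head = nodes, tail = c(nodes[-1], nodes[1]),
                           label = labels))
}

# a deterministic pool of random closed pairs with at most `max_edges` edges
# per side, used by oracle-vs-ILP comparisons
random_closed_pair <- function(seed, max_edges = 6) {
  n1 <- 3 + seed %% (max_edges - 2)
  n2 <- 3 + (seed + 1) %% (max_edges - 2)
  list(g1 = random_eulerian_graph(size = n1, n_nodes = 3, seed = seed),
       g2 = random_eulerian_graph(size = n2, n_nodes = 3, seed = seed + 1000))
}
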