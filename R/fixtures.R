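# run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' The two-triangle counterexample pair
#'
#' Two graphs, each consisting of two 3-cycles sharing one node. The first
#' spells the circular permutations of TTTGAA, the second of TTTAGA. Their
#' traversal edit distance is 2, but the flow-projection lower bound is 0:
#' the optimal flow decomposes into two disjoint cycles (TTT matched with
#' TTT, GAA with the rotation of AGA) and so the pair separates the exact
#' distance from its closed-trail cover lower bound.
#'
#' @return List with `g1` and `g2` (`labeled_graph`s, both closed, 5 nodes
#'   and 6 edges each).
#' @export
make_two_triangle_pair <- function() {
  triangle_pair <- function(labels1, labels2) {
    labeled_graph(data.frame(
      head = c("c", "t1", "t2", "c", "r1", "r2"),
      tail = c("t1", "t2", "c", "r1", "r2", "c"),
      label = c(labels1, labels2)))
  }
  list(g1 = triangle_pair(c("T", "T", "T"), c("G", "A", "A")),
       g2 = triangle_pair(c("T", "T", "T"), c("A", "G", "A")))
}

#' Generate an n-cycle graph
#'
#' A central cycle with `n - 1` peripheral cycles attached, emulating genomes
#' with repeats (segmental duplications, translocations): the class of
#' instances on which the gap between the exact distance and its cover lower
#' bound grows. With node attachment each peripheral cycle shares a single
#' node of the central cycle; with edge attachment the peripheral cycle
#' additionally duplicates a contiguous run of central-cycle edges
#' (multiplicity 2) and returns through fresh nodes. Labels are drawn
#' uniformly from `alphabet` under `seed`.
#'
#' @param n Total number of cycles (at least 2).
#' @param lengths Integer vector of the `n` cycle lengths (peripheral cycles
#'   first, central cycle last); all at least 1, central at least 3.
#' @param attachment `"node"` or `"edge"`.
#' @param shared Number of shared central edges per peripheral cycle when
#'   `attachment = "edge"` (must be < peripheral length).
#' @param alphabet Character vector of labels.
#' @param seed Integer seed; the same seed reproduces the same graph.
#' @return A closed, unidirectional `labeled_graph`.
#' @export
make_ncycle_graph <- function(n, lengths, attachment = c("node", "edge"),
                              shared = 1L, alphabet = c("A", "T", "C", "G"),
                              seed = 1L) {
  attachment <- match.arg(attachment)
  stopifnot(n >= 2, length(lengths) == n, all(lengths >= 1), lengths[n] >= 3)
  with_seed(seed, {
    Lc <- lengths[n]
    central <- sprintf("c%02d", seq_len(Lc))
    heads <- central
    tails <- c(central[-1], central[1])
    labels <- sample(alphabet, Lc, replace = TRUE)
    mult <- rep(1L, Lc)
    edges <- data.frame(head = heads, tail = tails, label = labels,
                        mult = mult)
    for (i in seq_len(n - 1)) {
      Lp <- lengths[i]
      attach_at <- ((i - 1L) %% Lc) + 1L
      if (attachment == "node" || shared <= 0) {
        hub <- central[attach_at]
        if (Lp == 1) {
          new_e <- data.frame(head = hub, tail = hub,
                              label = sample(alphabet, 1), mult = 1L)
        } else {
          per <- c(hub, sprintf("p%02d_%02d", i, seq_len(Lp - 1)), hub)
          new_e <- data.frame(head = per[-length(per)], tail = per[-1],
                              label = sample(alphabet, Lp, replace = TRUE),
                              mult = 1L)
        }
      } else {
        stopifnot(shared < Lp)
        # duplicate `shared` consecutive central edges, return via new nodes
        run <- ((attach_at - 1L + seq_len(shared) - 1L) %% Lc) + 1L
        dup <- edges[run, , drop = FALSE]
        ret_len <- Lp - shared
        from <- tails[run[length(run)]]
        to <- heads[run[1]]
        if (ret_len == 1) {
          ret <- data.frame(head = from, tail = to,
                            label = sample(alphabet, 1), mult = 1L)
        } else {
          mid <- sprintf("q%02d_%02d", i, seq_len(ret_len - 1))
          per <- c(from, mid, to)
          ret <- data.frame(head = per[-length(per)], tail = per[-1],
                            label = sample(alphabet, ret_len, replace = TRUE),
                            mult = 1L)
        }
        new_e <- rbind(dup, ret)
      }
      edges <- rbind(edges, new_e)
    }
    g <- labeled_graph(edges)
    kind <- validate_eulerian_unidirectional(g)
    stopifnot(kind$kind == "closed")
    g
  })
}

#' Hamiltonian-path reduction instance
#'
#' Builds, from a simple directed graph, the pair of Eulerian graphs used in
#' the reduction showing that the traversal edit distance is NP-hard: the
#' Eulerian closure of the input (vertex in/out splitting, a hub vertex, and
#' six labeled edge families over the alphabet \{a, b, c\}), with every
#' antiparallel edge pair split through dummy nodes into parallel
#' length-2 paths labeled (x, #); and a single cycle graph spelling
#' `q = a#(b#a#)^(n-1)(c#)^(2n-1)(c#b#)^(m+1)`. The input graph has a
#' Hamiltonian path exactly when the traversal edit distance between the two
#' outputs is 0.
#'
#' @param edges Data frame with columns `from`, `to`: the simple digraph (no
#'   self-loops, no parallel edges).
#' @param vertices Optional character vector of vertices (defaults to those
#'   appearing in `edges`).
#' @return A `reduction_instance`: list with `closure` (the Eulerian closure
#'   after splitting), `cycle` (the cycle graph), `q`, `n`, `m`.
#' @export
make_hamiltonian_reduction <- function(edges, vertices = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) stop("input graph must have no self-loops")
  if (anyDuplicated(paste(edges$from, edges$to))) {
    stop("input graph must have no parallel edges")
  }
  V <- sort(unique(c(edges$from, edges$to, as.character(vertices))))
  n <- length(V)
  m <- nrow(edges)
  vin <- function(v) paste0("in:", v)
  vout <- function(v) paste0("out:", v)
  hub <- "hub"
  prime <- rbind(
    data.frame(head = vin(V), tail = vout(V), label = "a"),          # E1
    data.frame(head = vout(edges$from), tail = vin(edges$to),
               label = "b"),                                          # E2
    data.frame(head = vout(V), tail = vin(V), label = "c"),          # E3
    data.frame(head = vin(edges$to), tail = vout(edges$from),
               label = "c"),                                          # E4
    data.frame(head = vin(V), tail = hub, label = "c"),              # E5
    data.frame(head = hub, tail = vin(V), label = "b"))              # E6
  stopifnot(nrow(prime) == 4 * n + 2 * m)
  # every edge of the closure participates in an antiparallel pair
  # (E1/E3, E2/E4, E5/E6); assert, then split each edge through a dummy node
  pk <- paste(prime$head, prime$tail)
  rk <- paste(prime$tail, prime$head)
  stopifnot(all(rk %in% pk))
  dummy <- sprintf("d%03d", seq_len(nrow(prime)))
  closure <- labeled_graph(rbind(
    data.frame(head = prime$head, tail = dummy, label = prime$label),
    data.frame(head = dummy, tail = prime$tail, label = "#")))
  stopifnot(n_edges(closure) == 2 * nrow(prime))
  q <- paste0("a#",
              strrep("b#a#", n - 1),
              strrep("c#", 2 * n - 1),
              strrep("c#b#", m + 1))
  stopifnot(nchar(q) == n_edges(closure))
  qc <- strsplit(q, "")[[1]]
  cyc_nodes <- sprintf("y%03d", seq_along(qc))
  cycle <- labeled_graph(data.frame(
    head = cyc_nodes, tail = c(cyc_nodes[-1], cyc_nodes[1]), label = qc))
  structure(list(closure = closure, cycle = cycle, q = q, n = n, m = m),
            class = "reduction_instance")
}

#' @export
print.reduction_instance <- function(x, ...) {
  cat(sprintf("reduction_instance: n = %d, m = %d, |E(closure)| = %d, |q| = %d\n",
              x$n, x$m, n_edges(x$closure), nchar(x$q)))
  invisible(x)
}

#' Generate a random sequence and a mutated copy
#'
#' The first sequence is uniform over ACGT; the second applies independent
#' per-position substitutions (to a different base) at the given rate.
#' Deterministic under `seed`. Intended as input to [build_debruijn()] for
#' sequence-scale benchmarks.
#'
#' @param length Sequence length.
#' @param rate Substitution probability per position, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Character vector of the two sequences.
#' @export
random_sequence_pair <- function(length, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1, length >= 1)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    s1 <- sample(bases, length, replace = TRUE)
    hit <- stats::runif(length) < rate
    s2 <- s1
    if (any(hit)) {
      s2[hit] <- vapply(s1[hit], function(b) sample(setdiff(bases, b), 1), "")
    }
    c(paste(s1, collapse = ""), paste(s2, collapse = ""))
  })
}

#' Generate a small random closed Eulerian graph
#'
#' Rejection sampling over random closed walks: a walk of `size` steps on at
#' most `n_nodes` nodes is drawn, closed back to its start, and kept if the
#' resulting multigraph is connected, unidirectional, and balanced. Used to
#' drive property tests and oracle comparisons on enumerable instances.
#'
#' @param size Number of edges.
#' @param n_nodes Maximum number of distinct nodes.
#' @param alphabet Labels to draw from.
#' @param seed Integer seed.
#' @return A closed `labeled_graph` with `size` edges.
#' @export
random_eulerian_graph <- function(size, n_nodes = 4, alphabet = c("A", "T", "C", "G"),
                                  seed = 1L) {
  stopifnot(size >= 1)
  with_seed(seed, {
    nodes <- sprintf("v%d", seq_len(n_nodes))
    for (attempt in 1:5000) {
      walk <- sample(nodes, size, replace = TRUE)
      heads <- walk
      tails <- c(walk[-1], walk[1])
      g <- try(labeled_graph(data.frame(
        head = heads, tail = tails,
        label = sample(alphabet, size, replace = TRUE))), silent = TRUE)
      if (inherits(g, "try-error")) next
      kind <- try(validate_eulerian_unidirectional(g), silent = TRUE)
      if (inherits(kind, "try-error") || kind$kind != "closed") next
      return(g)
    }
    stop("could not sample a valid closed graph; relax the parameters")
  })
}
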