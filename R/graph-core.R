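#' Construct an edge-labeled directed multigraph
#'
#' The central container of the package: a directed multigraph whose edges
#' carry single-character labels. Parallel edges with the same head, tail and
#' label are stored merged, with an integer multiplicity, so the edge multiset
#' is represented compactly. Whether the graph is a valid input for distance
#' computations (connected, unidirectional, Eulerian) is checked separately by
#' [validate_eulerian_unidirectional()].
#'
#' @param edges A data frame with columns `head`, `tail`, `label` and
#'   optionally `mult` (positive integer multiplicities, default 1). One row
#'   per edge (or per merged edge when `mult` is given).
#' @param nodes Optional character vector of node identifiers; nodes that
#'   appear in `edges` are always included. Use this to declare isolated
#'   nodes explicitly.
#' @return An object of class `labeled_graph` with components `nodes` (sorted
#'   character vector) and `edges` (merged edge data frame, sorted by
#'   head/tail/label, with `mult` column).
#' @examples
#' g <- labeled_graph(data.frame(head = c("u", "v"), tail = c("v", "u"),
#'                               label = c("A", "C")))
#' @export
labeled_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0) {
    stopifnot(all(c("head", "tail", "label") %in% names(edges)))
  } else {
    edges <- data.frame(head = character(), tail = character(),
                        label = character(), mult = integer())
  }
  edges$head <- as.character(edges$head)
  edges$tail <- as.character(edges$tail)
  edges$label <- as.character(edges$label)
  if (is.null(edges$mult)) edges$mult <- rep(1L, nrow(edges))
  if (nrow(edges) > 0) {
    if (any(nchar(edges$label) != 1L)) {
      stop("edge labels must be single characters; offending label(s): ",
           paste(unique(edges$label[nchar(edges$label) != 1L]), collapse = ", "))
    }
    if (any(edges$mult < 1L) || any(edges$mult != round(edges$mult))) {
      stop("edge multiplicities must be positive integers")
    }
    edges$mult <- as.integer(edges$mult)
  }
  merged <- merge_edge_table(edges)
  all_nodes <- sort(unique(c(merged$head, merged$tail, as.character(nodes))))
  structure(list(nodes = all_nodes, edges = merged), class = "labeled_graph")
}

# group an edge table by (head, tail, label) and sum multiplicities
merge_edge_table <- function(edges) {
  if (nrow(edges) == 0) {
    return(data.frame(head = character(), tail = character(),
                      label = character(), mult = integer()))
  }
  key <- paste(edges$head, edges$tail, edges$label, sep = "\x1f")
  mult <- tapply(edges$mult, key, sum)
  parts <- strsplit(names(mult), "\x1f", fixed = TRUE)
  out <- data.frame(head = vapply(parts, `[`, "", 1L),
                    tail = vapply(parts, `[`, "", 2L),
                    label = vapply(parts, `[`, "", 3L),
                    mult = as.integer(mult))
  out <- out[order(out$head, out$tail, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge parallel edges of a graph
#'
#' Groups edges by the (head, tail, label) triple and records the count as a
#' multiplicity. The multiset semantics are preserved: expanding multiplicities
#' recovers the input edge multiset. Edges between the same node pair with
#' *different* labels stay distinct, because they align differently and are
#' covered by separate projection constraints.
#'
#' @param g A `labeled_graph`.
#' @return A `labeled_graph` in merged form (the operation is idempotent).
#' @export
merge_parallel_edges <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  labeled_graph(g$edges, nodes = g$nodes)
}

#' Expand a merged graph back to one row per edge occurrence
#'
#' @param g A `labeled_graph`.
#' @return A data frame with one row per edge unit, columns `head`, `tail`,
#'   `label`, and `unit` (a stable 1-based identifier; units of the same
#'   merged edge are consecutive).
#' @export
expand_edges <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  e <- g$edges
  idx <- rep(seq_len(nrow(e)), e$mult)
  out <- data.frame(head = e$head[idx], tail = e$tail[idx],
                    label = e$label[idx], merged = idx)
  out$unit <- seq_len(nrow(out))
  out
}

#' Total number of edges (counting multiplicities)
#' @param g A `labeled_graph`.
#' @return Integer edge count of the multiset.
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  sum(g$edges$mult)
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("labeled_graph: %d nodes, %d edges (%d merged)\n",
              length(x$nodes), n_edges(x), nrow(x$edges)))
  invisible(x)
}

#' Validate that a graph is unidirectional and admits an Eulerian trail
#'
#' Inputs to the distance computations must be connected directed graphs with
#' no antiparallel edges between distinct nodes (self-loops are allowed) that
#' admit an Eulerian trail: either every node is balanced (closed trail), or
#' exactly one node has one excess out-edge and one node one excess in-edge
#' (open trail).
#'
#' @param g A non-empty `labeled_graph`.
#' @return A `trail_kind` object: list with `kind` (`"closed"` or `"open"`)
#'   and, for open trails, `start` and `end` node identifiers.
#' @export
validate_eulerian_unidirectional <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  e <- g$edges
  if (nrow(e) == 0) stop("graph has no edges")
  # antiparallel check on distinct node pairs
  pair <- paste(e$head, e$tail, sep = "\x1f")
  rev_pair <- paste(e$tail, e$head, sep = "\x1f")
  bad <- which(e$head != e$tail & rev_pair %in% pair)
  if (length(bad) > 0) {
    stop(sprintf("antiparallel edges between nodes '%s' and '%s'",
                 e$head[bad[1]], e$tail[bad[1]]))
  }
  # weak connectivity over all declared nodes
  ig <- igraph::graph_from_data_frame(e[, c("head", "tail")],
                                      vertices = g$nodes, directed = TRUE)
  if (igraph::count_components(ig, mode = "weak") != 1L) {
    stop("graph is not connected")
  }
  outd <- tapply(e$mult, e$head, sum)
  ind <- tapply(e$mult, e$tail, sum)
  bal <- setNames(numeric(length(g$nodes)), g$nodes)
  bal[names(outd)] <- bal[names(outd)] + outd
  bal[names(ind)] <- bal[names(ind)] - ind
  plus <- names(bal)[bal > 0]
  minus <- names(bal)[bal < 0]
  if (length(plus) == 0 && length(minus) == 0) {
    return(structure(list(kind = "closed", start = NULL, end = NULL),
                     class = "trail_kind"))
  }
  if (length(plus) == 1 && length(minus) == 1 &&
      bal[plus] == 1 && bal[minus] == -1) {
    return(structure(list(kind = "open", start = plus, end = minus),
                     class = "trail_kind"))
  }
  stop("degree condition violated: graph does not admit an Eulerian trail (",
       length(plus) + length(minus), " imbalanced nodes)")
}

#' @export
print.trail_kind <- function(x, ...) {
  if (x$kind == "closed") cat("closed Eulerian trail\n")
  else cat(sprintf("open Eulerian trail: %s -> %s\n", x$start, x$end))
  invisible(x)
}

#' Build a de Bruijn graph from a nucleotide sequence
#'
#' Nodes are the (k-1)-mers of the sequence; every k-mer occurrence
#' contributes one edge from its (k-1)-prefix to its (k-1)-suffix, labeled
#' with the k-mer's last character. In circular mode the sequence wraps, so
#' the graph has exactly `nchar(sequence)` edges and admits a closed Eulerian
#' trail; in linear mode there are `nchar(sequence) - k + 1` edges.
#'
#' @param sequence Character scalar over a finite alphabet (no `#`).
#' @param k Integer k-mer size, at least 2.
#' @param circular Logical; wrap the sequence end-to-start.
#' @return A `labeled_graph`. Errors if the sequence is too short or the
#'   resulting graph has antiparallel edges (reported with the node pair).
#' @examples
#' build_debruijn("ACGT", k = 3)
#' @export
build_debruijn <- function(sequence, k, circular = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, k >= 2)
  n <- nchar(sequence)
  if (grepl("#", sequence, fixed = TRUE)) {
    stop("'#' is a reserved character and cannot appear in input sequences")
  }
  if (!circular && n < k) {
    stop(sprintf("sequence too short: length %d < k = %d", n, k))
  }
  if (circular && n < k - 1) {
    stop(sprintf("sequence too short for circular mode: length %d < k-1 = %d",
                 n, k - 1))
  }
  s <- if (circular) paste0(sequence, substr(sequence, 1L, k - 1L)) else sequence
  m <- if (circular) n else n - k + 1L
  starts <- seq_len(m)
  kmers <- substring(s, starts, starts + k - 1L)
  edges <- data.frame(head = substr(kmers, 1L, k - 1L),
                      tail = substr(kmers, 2L, k),
                      label = substr(kmers, k, k))
  g <- labeled_graph(edges)
  # surface antiparallel pairs at build time with a de Bruijn-specific message
  e <- g$edges
  pair <- paste(e$head, e$tail, sep = "\x1f")
  rev_pair <- paste(e$tail, e$head, sep = "\x1f")
  bad <- which(e$head != e$tail & rev_pair %in% pair)
  if (length(bad) > 0) {
    stop(sprintf(paste0("de Bruijn graph is not unidirectional: antiparallel ",
                        "(k-1)-mer pair '%s' / '%s'"),
                 e$head[bad[1]], e$tail[bad[1]]))
  }
  g
}

#' Deterministic Eulerian trail of a graph
#'
#' Hierholzer-style edge-pairing walk with lexicographic tie-breaking: the walk
#' starts at the open trail's start node (or at `start`, defaulting to the
#' lexicographically smallest node, for closed graphs) and always follows the
#' smallest available (tail, label) key. Used to seed the boundary-matrix
#' formulation and to decode solutions; the result is reproducible.
#'
#' @param g A valid `labeled_graph`.
#' @param start Optional start node for closed graphs.
#' @return Integer vector of edge units (rows of [expand_edges()]) in trail
#'   order.
#' @export
eulerian_trail <- function(g, start = NULL) {
  kind <- validate_eulerian_unidirectional(g)
  units <- expand_edges(g)
  if (kind$kind == "open") {
    s0 <- kind$start
  } else {
    s0 <- if (is.null(start)) min(g$nodes[g$nodes %in% units$head]) else start
  }
  walk_units(units, s0, expected = nrow(units))
}

# Hierholzer walk over an explicit unit table; errors if not all units are
# consumed (disconnected selection). Returns unit ids in walk order.
walk_units <- function(units, start, expected = nrow(units)) {
  ord <- order(units$head, units$tail, units$label, units$unit)
  units_sorted <- units[ord, , drop = FALSE]
  # per-head index into sorted units
  by_head <- split(seq_len(nrow(units_sorted)), units_sorted$head)
  ptr <- lapply(by_head, function(ix) ix)  # remaining, in sorted order
  used <- logical(nrow(units_sorted))
  next_unused <- function(v) {
    ix <- ptr[[v]]
    if (is.null(ix)) return(NA_integer_)
    while (length(ix) > 0 && used[ix[1]]) ix <- ix[-1]
    ptr[[v]] <<- ix
    if (length(ix) == 0) NA_integer_ else ix[1]
  }
  stack_nodes <- start
  stack_edges <- integer(0)  # edge taken to reach stack_nodes[i] (0 for start)
  circuit <- integer(0)
  while (length(stack_nodes) > 0) {
    v <- stack_nodes[length(stack_nodes)]
    i <- next_unused(v)
    if (!is.na(i)) {
      used[i] <- TRUE
      stack_nodes <- c(stack_nodes, units_sorted$tail[i])
      stack_edges <- c(stack_edges, i)
    } else {
      if (length(stack_edges) > 0) {
        circuit <- c(circuit, stack_edges[length(stack_edges)])
        stack_edges <- stack_edges[-length(stack_edges)]
      }
      stack_nodes <- stack_nodes[-length(stack_nodes)]
    }
  }
  trail <- rev(circuit)
  if (length(trail) != expected) {
    stop("walk could not consume every edge: selection is disconnected")
  }
  units_sorted$unit[trail]
}

#' Spell the string of a trail
#'
#' Concatenates the labels along a sequence of edge units of a graph.
#'
#' @param g A `labeled_graph`.
#' @param trail Integer vector of edge units as returned by [eulerian_trail()].
#' @return Character scalar.
#' @export
spell_trail <- function(g, trail) {
  units <- expand_edges(g)
  paste(units$label[match(trail, units$unit)], collapse = "")
}
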