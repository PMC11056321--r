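#' Edit cost model
#'
#' Unit costs for the columns of an alignment between strings spelled by the
#' two graphs: diagonal edges cost `match` (labels equal) or `mismatch`
#' (labels differ), vertical/horizontal edges cost `indel`, and the
#' epsilon-labeled source/sink edges added by [augment_source_sink()] cost
#' `eps`. The defaults give the Levenshtein distance.
#'
#' @param match,mismatch,indel,eps Non-negative numbers.
#' @return A `cost_model` object.
#' @export
cost_model <- function(match = 0, mismatch = 1, indel = 1, eps = 0) {
  stopifnot(match >= 0, mismatch >= 0, indel >= 0, eps >= 0)
  structure(list(match = match, mismatch = mismatch, indel = indel, eps = eps),
            class = "cost_model")
}

# internal node-id helpers for the product graph
pair_id <- function(v1, v2) paste(v1, v2, sep = "\x1f")
SOURCE_ID <- "\x01s"
SINK_ID <- "\x01t"

#' Build the alignment (product) graph of two labeled graphs
#'
#' The alignment graph generalizes the string-alignment dynamic-programming
#' matrix: its vertices are pairs of input vertices, vertical edges advance
#' only in the first graph (a gap in the second), horizontal edges advance
#' only in the second, and diagonal edges advance in both and carry the
#' match/mismatch cost of their two projected labels. Edges are stored merged,
#' indexed by the pair of merged input edges they project to; multiplicities
#' are inherited (product of the two for diagonals).
#'
#' @param g1,g2 Valid `labeled_graph` inputs (checked).
#' @param costs A [cost_model()].
#' @return An `alignment_graph` object: node table, edge table (columns
#'   `head`, `tail`, `kind`, `cost`, `p1`, `p2`, `mult`), the inputs, their
#'   trail kinds, and an `augmented` flag.
#' @export
build_alignment_graph <- function(g1, g2, costs = cost_model()) {
  stopifnot(inherits(costs, "cost_model"))
  kind1 <- validate_eulerian_unidirectional(g1)
  kind2 <- validate_eulerian_unidirectional(g2)
  e1 <- g1$edges
  e2 <- g2$edges
  # vertical: one per (merged G1 edge, G2 node)
  iv <- expand.grid(i = seq_len(nrow(e1)), v = seq_along(g2$nodes))
  vert <- data.frame(head = pair_id(e1$head[iv$i], g2$nodes[iv$v]),
                     tail = pair_id(e1$tail[iv$i], g2$nodes[iv$v]),
                     kind = "vertical", cost = costs$indel,
                     p1 = iv$i, p2 = NA_integer_, mult = e1$mult[iv$i])
  # horizontal: one per (G1 node, merged G2 edge)
  ih <- expand.grid(v = seq_along(g1$nodes), j = seq_len(nrow(e2)))
  horiz <- data.frame(head = pair_id(g1$nodes[ih$v], e2$head[ih$j]),
                      tail = pair_id(g1$nodes[ih$v], e2$tail[ih$j]),
                      kind = "horizontal", cost = costs$indel,
                      p1 = NA_integer_, p2 = ih$j, mult = e2$mult[ih$j])
  # diagonal: one per (merged G1 edge, merged G2 edge)
  id <- expand.grid(i = seq_len(nrow(e1)), j = seq_len(nrow(e2)))
  diag_cost <- ifelse(e1$label[id$i] == e2$label[id$j], costs$match,
                      costs$mismatch)
  diag <- data.frame(head = pair_id(e1$head[id$i], e2$head[id$j]),
                     tail = pair_id(e1$tail[id$i], e2$tail[id$j]),
                     kind = "diagonal", cost = diag_cost,
                     p1 = id$i, p2 = id$j, mult = e1$mult[id$i] * e2$mult[id$j])
  edges <- rbind(vert, horiz, diag)
  edges <- edges[order(edges$kind, edges$head, edges$tail,
                       edges$p1, edges$p2, na.last = TRUE), , drop = FALSE]
  rownames(edges) <- NULL
  edges$id <- seq_len(nrow(edges))
  nodes <- data.frame(id = pair_id(rep(g1$nodes, each = length(g2$nodes)),
                                   rep(g2$nodes, times = length(g1$nodes))),
                      v1 = rep(g1$nodes, each = length(g2$nodes)),
                      v2 = rep(g2$nodes, times = length(g1$nodes)))
  structure(list(nodes = nodes, edges = edges, g1 = g1, g2 = g2,
                 costs = costs, kind1 = kind1, kind2 = kind2,
                 augmented = FALSE, anchors = NULL),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf("alignment_graph: %d product nodes, %d merged edges%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$augmented) " (augmented with s/t)" else ""))
  invisible(x)
}

#' Augment an alignment graph with source and sink nodes
#'
#' Adds a source node s and a sink node t whose epsilon-labeled edges attach
#' to every possible start/end of an Eulerian trail, making one formulation
#' cover open and closed inputs alike:
#' * one input open (start a, end b): s connects to the full row/column of a,
#'   t from the full row/column of b;
#' * both closed: deterministic anchor nodes a1, a2 (lexicographically
#'   smallest) and s connects to the whole row of a1 and column of a2 (t
#'   symmetrically), with the duplicate at (a1, a2) counted once;
#' * both open: a single s edge into (a1, a2) and a single edge (b1, b2) to t.
#'
#' @param ag An unaugmented `alignment_graph`.
#' @param kind1,kind2 Trail kinds of the inputs; default to those recorded at
#'   construction.
#' @return The augmented `alignment_graph`.
#' @export
augment_source_sink <- function(ag, kind1 = ag$kind1, kind2 = ag$kind2) {
  stopifnot(inherits(ag, "alignment_graph"))
  if (ag$augmented) stop("alignment graph is already augmented")
  V1 <- ag$g1$nodes
  V2 <- ag$g2$nodes
  if (kind1$kind == "open" && kind2$kind == "open") {
    src_to <- pair_id(kind1$start, kind2$start)
    snk_from <- pair_id(kind1$end, kind2$end)
    anchors <- list(a1 = kind1$start, a2 = kind2$start)
  } else if (kind1$kind == "open" && kind2$kind == "closed") {
    src_to <- pair_id(kind1$start, V2)
    snk_from <- pair_id(kind1$end, V2)
    anchors <- list(a1 = kind1$start, a2 = NULL)
  } else if (kind1$kind == "closed" && kind2$kind == "open") {
    src_to <- pair_id(V1, kind2$start)
    snk_from <- pair_id(V1, kind2$end)
    anchors <- list(a1 = NULL, a2 = kind2$start)
  } else {
    a1 <- min(V1)
    a2 <- min(V2)
    src_to <- unique(c(pair_id(a1, V2), pair_id(V1, a2)))
    snk_from <- src_to
    anchors <- list(a1 = a1, a2 = a2)
  }
  eps <- ag$costs$eps
  add <- rbind(
    data.frame(head = SOURCE_ID, tail = src_to, kind = "source", cost = eps,
               p1 = NA_integer_, p2 = NA_integer_, mult = 1L),
    data.frame(head = snk_from, tail = SINK_ID, kind = "sink", cost = eps,
               p1 = NA_integer_, p2 = NA_integer_, mult = 1L))
  add$id <- nrow(ag$edges) + seq_len(nrow(add))
  ag$edges <- rbind(ag$edges, add)
  ag$nodes <- rbind(ag$nodes,
                    data.frame(id = c(SOURCE_ID, SINK_ID),
                               v1 = NA_character_, v2 = NA_character_))
  ag$augmented <- TRUE
  ag$anchors <- anchors
  ag
}

#' Project a trail in the alignment graph onto one input graph
#'
#' Maps each edge of the trail that has a projection on the requested side to
#' the corresponding merged input edge, preserving order; edges with no
#' projection on that side (horizontal for side 1, vertical for side 2,
#' source/sink for both) are skipped.
#'
#' @param ag An `alignment_graph`.
#' @param trail Integer vector of alignment edge ids forming a contiguous
#'   walk.
#' @param side 1 or 2.
#' @return Integer vector of merged edge indices of the input graph.
#' @export
project_path <- function(ag, trail, side) {
  stopifnot(inherits(ag, "alignment_graph"), side %in% c(1, 2))
  ix <- match(trail, ag$edges$id)
  if (anyNA(ix)) stop("trail contains edges not in the alignment graph")
  if (length(ix) > 1) {
    if (any(ag$edges$tail[ix[-length(ix)]] != ag$edges$head[ix[-1]])) {
      stop("trail is not a contiguous walk")
    }
  }
  p <- if (side == 1) ag$edges$p1[ix] else ag$edges$p2[ix]
  p[!is.na(p)]
}
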