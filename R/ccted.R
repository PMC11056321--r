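#' Build the flow-projection lower-bound ILP
#'
#' The historically first ILP for the graph traversal edit distance: choose a
#' non-negative integer copy number x_e for every merged alignment edge,
#' minimizing total edge cost, subject to (i) projection constraints -- the
#' edges projecting to each input edge f must be selected exactly M_i(f)
#' times, where M_i(f) is f's multiplicity -- (ii) unit flow out of the
#' source and into the sink, and (iii) flow conservation at every product
#' node. Without connectivity constraints the optimum may decompose into
#' disjoint closed trails, so it is a lower bound on the traversal edit
#' distance; on inputs with closed Eulerian trails it equals the closed-trail
#' cover traversal edit distance (CCTED).
#'
#' @param ag An augmented `alignment_graph` (see [augment_source_sink()]).
#' @return A `milp_problem` with one variable `x<id>` per merged alignment
#'   edge.
#' @export
build_lower_bound_model <- function(ag) {
  stopifnot(inherits(ag, "alignment_graph"))
  if (!ag$augmented) stop("alignment graph must be augmented with s/t first")
  e <- ag$edges
  xn <- paste0("x", e$id)
  # tight but valid upper bounds: x_e cannot exceed the multiplicity of any
  # edge it projects to; epsilon edges carry at most the unit s-t flow
  m1 <- ag$g1$edges$mult[e$p1]
  m2 <- ag$g2$edges$mult[e$p2]
  ub <- pmin(ifelse(is.na(m1), Inf, m1), ifelse(is.na(m2), Inf, m2))
  ub[e$kind %in% c("source", "sink")] <- 1
  p <- milp_problem()
  milp_add_variables(p, xn, type = "integer", lb = 0, ub = ub, obj = e$cost)
  # projection constraints, one per merged input edge
  for (i in seq_len(nrow(ag$g1$edges))) {
    sel <- which(!is.na(e$p1) & e$p1 == i)
    milp_add_constraint(p, setNames(rep(1, length(sel)), xn[sel]), "==",
                        ag$g1$edges$mult[i], name = paste0("proj1_", i))
  }
  for (j in seq_len(nrow(ag$g2$edges))) {
    sel <- which(!is.na(e$p2) & e$p2 == j)
    milp_add_constraint(p, setNames(rep(1, length(sel)), xn[sel]), "==",
                        ag$g2$edges$mult[j], name = paste0("proj2_", j))
  }
  # unit source/sink flow
  src <- which(e$kind == "source")
  snk <- which(e$kind == "sink")
  milp_add_constraint(p, setNames(rep(1, length(src)), xn[src]), "==", 1,
                      name = "source_flow")
  milp_add_constraint(p, setNames(rep(1, length(snk)), xn[snk]), "==", 1,
                      name = "sink_flow")
  # flow conservation at every product node
  product_nodes <- ag$nodes$id[!(ag$nodes$id %in% c(SOURCE_ID, SINK_ID))]
  out_by <- split(seq_len(nrow(e)), e$head)
  in_by <- split(seq_len(nrow(e)), e$tail)
  for (v in product_nodes) {
    oi <- out_by[[v]]
    ii <- in_by[[v]]
    if (is.null(oi) && is.null(ii)) next
    coefs <- c(setNames(rep(1, length(oi)), xn[oi]),
               setNames(rep(-1, length(ii)), xn[ii]))
    milp_add_constraint(p, coefs, "==", 0, name = paste0("flow_", v))
  }
  p
}

#' Compute the flow-projection lower bound / CCTED
#'
#' Builds the augmented alignment graph of the two inputs, solves the
#' lower-bound ILP, and returns its optimal value. When both inputs admit
#' closed Eulerian trails this value is exactly the closed-trail cover
#' traversal edit distance (CCTED): the minimum, over all decompositions of
#' each graph into edge-disjoint closed trails, of a minimum-cost matching
#' between the two trail covers under the (rotation-free) traversal edit
#' distance, where an unmatched trail costs its length. For open inputs the
#' value is reported only as a lower bound on the traversal edit distance.
#'
#' @param g1,g2 Valid `labeled_graph` inputs.
#' @param costs A [cost_model()].
#' @param relax Solve the LP relaxation instead (value then bounds the ILP
#'   from below).
#' @param time_limit,seed Passed to [solve_milp()].
#' @return List with `value`, `solution` (a `milp_solution`), `ag` (the
#'   augmented alignment graph) and `is_ccted` (TRUE when both inputs are
#'   closed).
#' @export
solve_ccted <- function(g1, g2, costs = cost_model(), relax = FALSE,
                        time_limit = NULL, seed = NULL) {
  ag <- augment_source_sink(build_alignment_graph(g1, g2, costs))
  p <- build_lower_bound_model(ag)
  sol <- solve_milp(p, relax = relax, time_limit = time_limit, seed = seed)
  if (sol$status != "optimal") {
    stop("lower-bound model did not solve to optimality: ", sol$status)
  }
  list(value = sol$objective, solution = sol, ag = ag,
       is_ccted = ag$kind1$kind == "closed" && ag$kind2$kind == "closed")
}

# expand a solution of the lower-bound model into per-unit selected edges
selected_units <- function(ag, sol) {
  e <- ag$edges
  x <- sol$assignment[paste0("x", e$id)]
  cnt <- as.integer(round(x))
  if (any(cnt < 0)) stop("negative edge selection in solution")
  idx <- rep(seq_len(nrow(e)), cnt)
  data.frame(edge = e$id[idx], head = e$head[idx], tail = e$tail[idx],
             kind = e$kind[idx], cost = e$cost[idx], p1 = e$p1[idx],
             p2 = e$p2[idx], label = NA)
}

#' Decode a lower-bound solution into matched closed-trail covers
#'
#' Peels trails one at a time from the subgraph selected by an optimal
#' solution of the lower-bound ILP (epsilon source/sink edges dropped). Each
#' peeled alignment trail projects to a closed trail in each input graph;
#' jointly the projections form an edge-disjoint closed-trail cover of each
#' input, and the per-trail costs sum to the ILP objective (when epsilon
#' edges cost 0). Components consisting purely of vertical (resp. horizontal)
#' edges correspond to a trail of the first (resp. second) graph matched with
#' the empty item.
#'
#' Peeling is deterministic: walks start at the lexicographically smallest
#' node with remaining out-edges and always follow the smallest remaining
#' edge key.
#'
#' @param ag The augmented `alignment_graph` used to build the model.
#' @param sol An optimal `milp_solution` of [build_lower_bound_model()].
#' @return A `cover_matching`: list with `pairs` (data frame with `str1`,
#'   `str2` -- `NA` for the empty side -- and `cost`) and `total`.
#' @export
decode_cover_matching <- function(ag, sol) {
  units <- selected_units(ag, sol)
  units <- units[!(units$kind %in% c("source", "sink")), , drop = FALSE]
  units$unit <- seq_len(nrow(units))
  pairs <- list()
  remaining <- units
  # the s-t component, stripped of its epsilon edges, may be an open walk at
  # the alignment level; peel it first, from the unique imbalanced node
  repeat {
    if (nrow(remaining) == 0) break
    outd <- table(remaining$head)
    ind <- table(remaining$tail)
    nodes <- union(names(outd), names(ind))
    bal <- setNames(numeric(length(nodes)), nodes)
    bal[names(outd)] <- bal[names(outd)] + as.numeric(outd)
    bal[names(ind)] <- bal[names(ind)] - as.numeric(ind)
    start <- if (any(bal > 0)) {
      if (sum(bal > 0) > 1 || max(bal) > 1) {
        stop("selected subgraph violates flow conservation")
      }
      names(bal)[bal > 0]
    } else {
      min(remaining$head)
    }
    trail <- peel_trail(remaining, start)
    picked <- remaining[match(trail, remaining$unit), , drop = FALSE]
    remaining <- remaining[!(remaining$unit %in% trail), , drop = FALSE]
    p1 <- picked$p1[!is.na(picked$p1)]
    p2 <- picked$p2[!is.na(picked$p2)]
    s1 <- if (length(p1)) paste(ag$g1$edges$label[p1], collapse = "") else NA
    s2 <- if (length(p2)) paste(ag$g2$edges$label[p2], collapse = "") else NA
    pairs[[length(pairs) + 1L]] <-
      data.frame(str1 = s1, str2 = s2, cost = sum(picked$cost),
                 n_edges = nrow(picked))
  }
  pairs <- do.call(rbind, pairs)
  structure(list(pairs = pairs, total = sum(pairs$cost)),
            class = "cover_matching")
}

# greedy walk from `start` over the remaining unit table until stuck;
# returns the unit ids of one trail (closed unless start is imbalanced)
peel_trail <- function(units, start) {
  ord <- order(units$edge, units$unit)
  u <- units[ord, , drop = FALSE]
  used <- logical(nrow(u))
  cur <- start
  picked <- integer(0)
  repeat {
    cand <- which(!used & u$head == cur)
    if (length(cand) == 0) break
    i <- cand[1]
    used[i] <- TRUE
    picked <- c(picked, u$unit[i])
    cur <- u$tail[i]
  }
  if (length(picked) == 0) stop("no edges to peel from node ", start)
  picked
}

#' @export
print.cover_matching <- function(x, ...) {
  cat(sprintf("cover_matching: %d trail pair(s), total cost %g\n",
              nrow(x$pairs), x$total))
  for (i in seq_len(nrow(x$pairs))) {
    cat(sprintf("  [%s] ~ [%s]  cost %g\n",
                ifelse(is.na(x$pairs$str1[i]), "-", x$pairs$str1[i]),
                ifelse(is.na(x$pairs$str2[i]), "-", x$pairs$str2[i]),
                x$pairs$cost[i]))
  }
  invisible(x)
}

#' Build the boundary-matrix (2-simplex) formulation
#'
#' The second historical formulation, stated over the *unmerged* alignment
#' graph of two closed inputs: every pair of one edge unit per input spans two
#' oriented triangles (vertical-then-horizontal and horizontal-then-vertical),
#' and the boundary operator maps each triangle to a signed sum of its three
#' edges (+1 on the two gap edges, -1 on the diagonal). The feasible set is
#' `x = x_init + B y` with `x` non-negative integers, `y` free integers per
#' triangle, and `x_init` the indicator of one Eulerian trail of the first
#' graph laid along the column of an anchor node of the second, plus one
#' trail of the second laid along the row of an anchor of the first. The
#' optimum equals the flow-projection lower bound.
#'
#' @param ag An *unaugmented* `alignment_graph` of two closed inputs.
#' @return List with `problem` (a `milp_problem`) and `model` (edge table,
#'   simplex count, `x_init`).
#' @export
build_simplex_model <- function(ag) {
  stopifnot(inherits(ag, "alignment_graph"))
  if (ag$augmented) stop("simplex model is stated on the unaugmented graph")
  if (ag$kind1$kind != "closed" || ag$kind2$kind != "closed") {
    stop("simplex model requires closed inputs")
  }
  u1 <- expand_edges(ag$g1)
  u2 <- expand_edges(ag$g2)
  n1 <- nrow(u1); n2 <- nrow(u2)
  V1 <- ag$g1$nodes; V2 <- ag$g2$nodes
  costs <- ag$costs
  # unmerged alignment edge table with dense index
  vert <- expand.grid(i = seq_len(n1), v = seq_along(V2))
  horiz <- expand.grid(v = seq_along(V1), j = seq_len(n2))
  diag <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  nv <- nrow(vert); nh <- nrow(horiz); nd <- nrow(diag)
  vid <- function(i, v) (v - 1L) * n1 + i               # 1..nv
  hid <- function(v, j) nv + (j - 1L) * length(V1) + v  # nv+1..nv+nh
  did <- function(i, j) nv + nh + (j - 1L) * n1 + i
  cost <- c(rep(costs$indel, nv + nh),
            ifelse(u1$label[diag$i] == u2$label[diag$j], costs$match,
                   costs$mismatch))
  ne <- nv + nh + nd
  # x_init: trail of G1 along the column of anchor s2, trail of G2 along the
  # row of anchor s1 (anchors: lexicographically smallest nodes)
  s1 <- min(V1); s2 <- min(V2)
  x_init <- numeric(ne)
  tr1 <- eulerian_trail(ag$g1, start = s1)
  x_init[vid(tr1, match(s2, V2))] <- x_init[vid(tr1, match(s2, V2))] + 1
  tr2 <- eulerian_trail(ag$g2, start = s2)
  x_init[hid(match(s1, V1), tr2)] <- x_init[hid(match(s1, V1), tr2)] + 1
  # boundary matrix columns: 2 per (unit1, unit2)
  sim <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  i <- sim$i; j <- sim$j
  h1 <- match(u1$head[i], V1); t1 <- match(u1$tail[i], V1)
  h2 <- match(u2$head[j], V2); t2 <- match(u2$tail[j], V2)
  ns <- nrow(sim)
  # triangle A: [(u1,u2),(v1,u2),(v1,v2)]: +vert(i,h2) +horiz(t1,j) -diag(i,j)
  # triangle B: [(u1,u2),(u1,v2),(v1,v2)]: +horiz(h1,j) +vert(i,t2) -diag(i,j)
  col_a <- seq_len(ns)
  col_b <- ns + seq_len(ns)
  tri_rows <- c(vid(i, h2), hid(t1, j), did(i, j),
                hid(h1, j), vid(i, t2), did(i, j))
  tri_cols <- c(col_a, col_a, col_a, col_b, col_b, col_b)
  tri_vals <- c(rep(1, ns), rep(1, ns), rep(-1, ns),
                rep(1, ns), rep(1, ns), rep(-1, ns))
  p <- milp_problem()
  xn <- paste0("x", seq_len(ne))
  yn <- paste0("y", seq_len(2L * ns))
  milp_add_variables(p, xn, type = "integer", lb = 0, ub = Inf, obj = cost)
  milp_add_variables(p, yn, type = "integer", lb = -Inf, ub = Inf, obj = 0)
  by_row <- split(data.frame(col = tri_cols, val = tri_vals), tri_rows)
  for (r in seq_len(ne)) {
    coefs <- setNames(1, xn[r])
    br <- by_row[[as.character(r)]]
    if (!is.null(br)) {
      yc <- tapply(-br$val, br$col, sum)  # move B y to the left-hand side
      yc <- yc[yc != 0]
      coefs <- c(coefs, setNames(as.numeric(yc),
                                 yn[as.integer(names(yc))]))
    }
    milp_add_constraint(p, coefs, "==", x_init[r], name = paste0("chain_", r))
  }
  list(problem = p,
       model = list(n_edges = ne, n_simplices = 2L * ns, x_init = x_init,
                    cost = cost))
}

#' Solve the boundary-matrix formulation
#'
#' Cross-validation entry point: on closed inputs its optimum equals the
#' flow-projection lower bound of [solve_ccted()].
#'
#' @inheritParams solve_ccted
#' @return List with `value` and `solution`.
#' @export
solve_simplex_lb <- function(g1, g2, costs = cost_model(), relax = FALSE,
                             time_limit = NULL, seed = NULL) {
  ag <- build_alignment_graph(g1, g2, costs)
  sm <- build_simplex_model(ag)
  sol <- solve_milp(sm$problem, relax = relax, time_limit = time_limit,
                    seed = seed)
  if (sol$status != "optimal") {
    stop("simplex model did not solve to optimality: ", sol$status)
  }
  list(value = sol$objective, solution = sol)
}
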