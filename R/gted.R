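#' Find strongly connected components violating the one-trail requirement
#'
#' Given a feasible flow solution, builds the subgraph induced by edges with
#' positive value and computes its strongly connected components. A component
#' is violating when it contains at least one selected edge, does not contain
#' the sink, and no selected edge leaves it: such a component is a closed
#' sub-solution disconnected from the s-t trail. For each violating
#' component the returned record carries the merged edges inside it (E(C)),
#' all alignment edges leaving it (the cut), and the multiplicity capacity
#' W(C) used to linearize the conditional connectivity constraint.
#'
#' @param ag An augmented `alignment_graph`.
#' @param sol A `milp_solution` feasible for the flow constraints.
#' @return List of `scc_constraint` records (empty when the selection is one
#'   connected s-t trail).
#' @export
find_violating_sccs <- function(ag, sol) {
  e <- ag$edges
  x <- sol$assignment[paste0("x", e$id)]
  sel <- which(round(x) > 0)
  if (length(sel) == 0) return(list())
  verts <- unique(c(e$head[sel], e$tail[sel]))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$head[sel], to = e$tail[sel]),
    vertices = verts, directed = TRUE)
  comp <- igraph::components(ig, mode = "strong")
  membership <- comp$membership[verts]
  names(membership) <- verts
  out <- list()
  for (cid in seq_len(comp$no)) {
    cn <- verts[membership == cid]
    if (SINK_ID %in% cn) next
    internal <- sel[e$head[sel] %in% cn & e$tail[sel] %in% cn]
    if (length(internal) == 0) next
    leaving_sel <- sel[e$head[sel] %in% cn & !(e$tail[sel] %in% cn)]
    if (length(leaving_sel) > 0) next
    # cut edges over the full alignment graph, not just the selection
    cut <- which(e$head %in% cn & !(e$tail %in% cn))
    m1 <- ag$g1$edges$mult[e$p1[internal]]
    m2 <- ag$g2$edges$mult[e$p2[internal]]
    W <- sum(pmax(ifelse(is.na(m1), 0, m1), ifelse(is.na(m2), 0, m2)))
    out[[length(out) + 1L]] <-
      structure(list(nodes = cn, edges = e$id[internal],
                     cut = e$id[cut], W = W),
                class = "scc_constraint")
  }
  out
}

# add the linearized connectivity constraints for one violating component
add_scc_constraints <- function(p, con, beta_name) {
  xe <- paste0("x", con$edges)
  xc <- paste0("x", con$cut)
  nE <- length(con$edges)
  milp_add_variables(p, beta_name, type = "binary")
  # sum_{E(C)} x >= |E(C)| beta
  milp_add_constraint(p, c(setNames(rep(1, nE), xe),
                           setNames(-nE, beta_name)), ">=", 0,
                      name = paste0(beta_name, "_lb"))
  # sum_{E(C)} x - |E(C)| + 1 - W(C) beta <= 0
  milp_add_constraint(p, c(setNames(rep(1, nE), xe),
                           setNames(-con$W, beta_name)), "<=", nE - 1,
                      name = paste0(beta_name, "_trigger"))
  # sum_{cut} x >= beta
  milp_add_constraint(p, c(setNames(rep(1, length(xc)), xc),
                           setNames(-1, beta_name)), ">=", 0,
                      name = paste0(beta_name, "_exit"))
  invisible(p)
}

#' Exact traversal edit distance by iterative constraint generation
#'
#' Solves the exponential-family formulation lazily: start from the
#' flow-projection lower-bound model, solve, locate strongly connected
#' components of the selected subgraph that are disconnected from the s-t
#' trail, add for each the linearized conditional constraint "if all its
#' edges are used, an edge must leave it", and re-solve until the selection
#' is a single s-t trail. Generated constraints are globally valid and
#' persist across iterations; all violating components found in an iteration
#' are added at once. The objective sequence is non-decreasing and the final
#' value is the exact traversal edit distance.
#'
#' @param g1,g2 Valid `labeled_graph` inputs.
#' @param costs A [cost_model()].
#' @param max_iterations Safety cap; when exceeded the current (still valid)
#'   lower bound is returned with `optimal = FALSE`.
#' @param time_limit,seed Per-solve settings for [solve_milp()].
#' @param quiet Suppress the per-iteration log line.
#' @return List with `value`, `trail` (a `trail_solution`, `NULL` when not
#'   optimal), `iterations`, `log` (data frame: iteration, objective,
#'   violations, constraints), and `optimal`.
#' @export
solve_gted_iterative <- function(g1, g2, costs = cost_model(),
                                 max_iterations = 1000, time_limit = NULL,
                                 seed = NULL, quiet = TRUE) {
  ag <- augment_source_sink(build_alignment_graph(g1, g2, costs))
  p <- build_lower_bound_model(ag)
  log <- data.frame(iteration = integer(), objective = numeric(),
                    violations = integer(), constraints = integer())
  n_beta <- 0L
  for (it in seq_len(max_iterations)) {
    sol <- solve_milp(p, time_limit = time_limit, seed = seed)
    if (sol$status != "optimal") {
      stop("iterative model did not solve to optimality: ", sol$status)
    }
    viol <- find_violating_sccs(ag, sol)
    log <- rbind(log, data.frame(iteration = it, objective = sol$objective,
                                 violations = length(viol),
                                 constraints = 3L * n_beta))
    if (!quiet) {
      message(sprintf("iteration %d: objective %g, %d violating component(s), %d cumulative constraints",
                      it, sol$objective, length(viol), 3L * n_beta))
    }
    if (length(viol) == 0) {
      trail <- extract_trail_and_alignment(ag, sol)
      trail$iterations <- it
      return(list(value = sol$objective, trail = trail, iterations = it,
                  log = log, optimal = TRUE))
    }
    for (con in viol) {
      n_beta <- n_beta + 1L
      add_scc_constraints(p, con, sprintf("beta%d", n_beta))
    }
  }
  list(value = sol$objective, trail = NULL, iterations = max_iterations,
       log = log, optimal = FALSE)
}

#' Build the compact ordering-variable ILP
#'
#' Extends the flow-projection model with Miller-Tucker-Zemlin-style ordering
#' variables that force the selection to be a single s-t trail: every edge e
#' gets a non-negative integer order variable d_e (the sum of the step
#' indices of e's selected copies) and a binary indicator y_e of e being
#' unused. At every internal node the outgoing order total exceeds the
#' incoming order total by exactly the number of selected out-copies; the
#' source edge has order 1 and the sink order equals the total number of
#' selected copies. Summing the node constraints over any disconnected
#' strongly connected component yields 0 on the left but a positive count on
#' the right, so disconnected selections are infeasible. The big-M constants
#' use the total (multiplicity-expanded) alignment edge count N: x_e + N y_e
#' >= 1 and d_e <= N^2 (1 - y_e).
#'
#' @param ag An augmented `alignment_graph`.
#' @return A `milp_problem` with variables `x<id>`, `d<id>`, `y<id>`.
#' @export
build_compact_model <- function(ag) {
  p <- build_lower_bound_model(ag)
  e <- ag$edges
  xn <- paste0("x", e$id)
  dn <- paste0("d", e$id)
  yn <- paste0("y", e$id)
  N <- sum(e$mult)  # total edge count, counting multiplicities
  milp_add_variables(p, dn, type = "integer", lb = 0, ub = N^2)
  milp_add_variables(p, yn, type = "binary")
  product_nodes <- ag$nodes$id[!(ag$nodes$id %in% c(SOURCE_ID, SINK_ID))]
  out_by <- split(seq_len(nrow(e)), e$head)
  in_by <- split(seq_len(nrow(e)), e$tail)
  for (v in product_nodes) {
    oi <- out_by[[v]]
    ii <- in_by[[v]]
    if (is.null(oi) && is.null(ii)) next
    coefs <- c(setNames(rep(1, length(oi)), dn[oi]),
               setNames(rep(-1, length(ii)), dn[ii]),
               setNames(rep(-1, length(oi)), xn[oi]))
    milp_add_constraint(p, coefs, "==", 0, name = paste0("order_", v))
  }
  src <- which(e$kind == "source")
  snk <- which(e$kind == "sink")
  milp_add_constraint(p, setNames(rep(1, length(src)), dn[src]), "==", 1,
                      name = "order_source")
  milp_add_constraint(p, c(setNames(rep(1, length(snk)), dn[snk]),
                           setNames(rep(-1, nrow(e)), xn)), "==", 0,
                      name = "order_sink")
  for (i in seq_len(nrow(e))) {
    milp_add_constraint(p, setNames(c(1, N), c(xn[i], yn[i])), ">=", 1,
                        name = paste0("use_", e$id[i]))
    milp_add_constraint(p, setNames(c(1, N^2), c(dn[i], yn[i])), "<=", N^2,
                        name = paste0("dcap_", e$id[i]))
  }
  p
}

#' Exact traversal edit distance via the compact formulation
#'
#' @inheritParams solve_gted_iterative
#' @param relax Solve the LP relaxation (returns only a bound; no decoding).
#' @return List with `value`, `trail` (a `trail_solution`, `NULL` under
#'   `relax`), and `solution`.
#' @export
solve_gted_compact <- function(g1, g2, costs = cost_model(), relax = FALSE,
                               time_limit = NULL, seed = NULL) {
  ag <- augment_source_sink(build_alignment_graph(g1, g2, costs))
  p <- build_compact_model(ag)
  sol <- solve_milp(p, relax = relax, time_limit = time_limit, seed = seed)
  if (sol$status != "optimal") {
    stop("compact model did not solve to optimality: ", sol$status)
  }
  trail <- if (!relax) extract_trail_and_alignment(ag, sol) else NULL
  list(value = sol$objective, trail = trail, solution = sol)
}

#' Decode a one-trail solution into an alignment
#'
#' Walks the selected subgraph from the source to the sink (Hierholzer-style,
#' consuming each selected merged edge exactly its value, lexicographic edge
#' order for tie-breaks) and emits the implied alignment: a diagonal edge
#' contributes a match/mismatch column, a vertical edge a
#' character-over-gap column, a horizontal edge a gap-over-character column;
#' epsilon edges contribute nothing. The recomputed alignment cost must equal
#' the solution objective (checked). The projections of the trail are
#' Eulerian trails of the inputs.
#'
#' @param ag The augmented `alignment_graph`.
#' @param sol An optimal `milp_solution` whose selection is one connected
#'   s-t flow (errors otherwise).
#' @return A `trail_solution`: list with `edges` (alignment edge ids in walk
#'   order), `aligned1`, `aligned2` (gapped strings), `cost`, `iterations`.
#' @export
extract_trail_and_alignment <- function(ag, sol) {
  e <- ag$edges
  x <- sol$assignment[paste0("x", e$id)]
  cnt <- as.integer(round(x))
  idx <- rep(seq_len(nrow(e)), cnt)
  units <- data.frame(head = e$head[idx], tail = e$tail[idx],
                      label = "", unit = seq_along(idx), row = idx)
  trail_units <- walk_units(units, SOURCE_ID, expected = nrow(units))
  rows <- units$row[match(trail_units, units$unit)]
  if (e$tail[rows[length(rows)]] != SINK_ID) {
    stop("decoded walk does not end at the sink")
  }
  lab1 <- ifelse(is.na(e$p1[rows]), "-", ag$g1$edges$label[e$p1[rows]])
  lab2 <- ifelse(is.na(e$p2[rows]), "-", ag$g2$edges$label[e$p2[rows]])
  keep <- !(e$kind[rows] %in% c("source", "sink"))
  cost <- sum(e$cost[rows])
  if (abs(cost - sol$objective) > 1e-6) {
    stop("decoded alignment cost does not match the objective")
  }
  structure(list(edges = e$id[rows], aligned1 = paste(lab1[keep], collapse = ""),
                 aligned2 = paste(lab2[keep], collapse = ""), cost = cost,
                 iterations = NA_integer_),
            class = "trail_solution")
}

#' @export
print.trail_solution <- function(x, ...) {
  cat(sprintf("trail_solution: cost %g\n  %s\n  %s\n", x$cost, x$aligned1,
              x$aligned2))
  invisible(x)
}
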