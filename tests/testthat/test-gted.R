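test_that("violating component detection separates disjoint cycles", {
  p <- make_two_triangle_pair()
  ag <- augment_source_sink(build_alignment_graph(p$g1, p$g2))
  model <- build_lower_bound_model(ag)
  sol <- solve_milp(model)
  expect_equal(sol$objective, 0)
  viol <- find_violating_sccs(ag, sol)
  # the zero-cost optimum decomposes into disjoint cycles off the s-t path
  expect_gte(length(viol), 1)
  expect_lte(length(viol), 2)
  for (v in viol) {
    e <- ag$edges[match(v$edges, ag$edges$id), ]
    expect_true(all(e$head %in% v$nodes & e$tail %in% v$nodes))
    cut <- ag$edges[match(v$cut, ag$edges$id), ]
    expect_true(all(cut$head %in% v$nodes & !(cut$tail %in% v$nodes)))
    expect_gte(v$W, length(v$edges))
  }

  # a hand-built connected s-t selection has no violating component
  same <- solve_gted_compact(single_edge("A"), single_edge("A", "p", "q"))
  ag2 <- augment_source_sink(build_alignment_graph(single_edge("A"),
                                                   single_edge("A", "p", "q")))
  expect_length(find_violating_sccs(ag2, same$solution), 0)
})

test_that("hand-built disjoint cycle is flagged by component detection", {
  # triangle x triangle: select the zero-cost diagonal cycle NOT through the
  # s-t path plus an epsilon path; the cycle must be returned
  g <- triangle(c("A", "C", "G"))
  ag <- augment_source_sink(build_alignment_graph(g, triangle(c("A", "C", "G"),
                                                              c("p", "q", "r"))))
  e <- ag$edges
  # diagonal match cycle at offset 1: (a,q)->(b,r)->(c,p)->(a,q): mismatches,
  # still a valid cycle; epsilon path s->(a,p)->t
  dd <- e[e$kind == "diagonal", ]
  cyc <- integer(0)
  cur <- paste("a", "q", sep = "\x1f")
  for (i in 1:3) {
    row <- dd[dd$head == cur, ][1, ]
    cyc <- c(cyc, row$id)
    cur <- row$tail
  }
  expect_equal(cur, paste("a", "q", sep = "\x1f"))
  spath <- c(e$id[e$kind == "source" & e$tail == paste("a", "p", sep = "\x1f")],
             e$id[e$kind == "sink" & e$head == paste("a", "p", sep = "\x1f")])
  x <- setNames(rep(0, nrow(e)), paste0("x", e$id))
  x[paste0("x", c(cyc, spath))] <- 1
  fake <- structure(list(status = "optimal", objective = sum(e$cost[match(c(cyc, spath), e$id)]),
                         assignment = x), class = "milp_solution")
  viol <- find_violating_sccs(ag, fake)
  expect_length(viol, 1)
  expect_setequal(viol[[1]]$edges, cyc)
})

test_that("iterative constraint generation reaches the exact distance", {
  p <- make_two_triangle_pair()
  r <- solve_gted_iterative(p$g1, p$g2)
  expect_equal(r$value, 2)
  expect_true(r$optimal)
  expect_gte(r$iterations, 2)  # the first solve attains 0 via disjoint cycles
  # objective sequence is non-decreasing (constraints are only added)
  expect_true(all(diff(r$log$objective) >= -1e-9))
  # decoded alignment is consistent
  expect_equal(r$trail$cost, 2)
  expect_equal(levenshtein(gsub("-", "", r$trail$aligned1),
                           gsub("-", "", r$trail$aligned2)), 2)

  same <- solve_gted_iterative(p$g1, p$g1)
  expect_equal(same$value, 0)
  expect_true(same$optimal)

  # iteration cap returns a valid bound and flags non-optimality
  capped <- solve_gted_iterative(p$g1, p$g2, max_iterations = 1)
  expect_false(capped$optimal)
  expect_lte(capped$value, 2)
})

test_that("compact ordering formulation reaches the exact distance", {
  p <- make_two_triangle_pair()
  r <- solve_gted_compact(p$g1, p$g2)
  expect_equal(r$value, 2)

  rr <- solve_gted_compact(single_edge("A"), single_edge("A", "p", "q"))
  expect_equal(rr$value, 0)
  expect_length(rr$trail$edges, 3)  # source, diagonal, sink
  expect_equal(rr$trail$aligned1, "A")
  expect_equal(rr$trail$aligned2, "A")

  expect_equal(solve_gted_compact(single_edge("A"),
                                  single_edge("C", "p", "q"))$value, 1)
})

test_that("both exact formulations agree with the brute-force reference", {
  for (s in 1:6) {
    pr <- random_closed_pair(s)
    bg <- brute_force_gted(pr$g1, pr$g2)
    expect_equal(solve_gted_compact(pr$g1, pr$g2)$value, bg)
    ri <- solve_gted_iterative(pr$g1, pr$g2)
    expect_equal(ri$value, bg)
    expect_true(ri$optimal)
  }
})

test_that("decoded trail projections cover each input's edge multiset", {
  p <- make_two_triangle_pair()
  ag <- augment_source_sink(build_alignment_graph(p$g1, p$g2))
  model <- build_compact_model(ag)
  sol <- solve_milp(model)
  tr <- extract_trail_and_alignment(ag, sol)
  for (side in 1:2) {
    g <- if (side == 1) p$g1 else p$g2
    pr <- project_path(ag, tr$edges, side)
    covered <- table(factor(pr, levels = seq_len(nrow(g$edges))))
    expect_equal(as.integer(covered), g$edges$mult)
    # the projection is a contiguous closed walk in the input graph
    heads <- g$edges$head[pr]
    tails <- g$edges$tail[pr]
    expect_true(all(tails[-length(tails)] == heads[-1]))
  }
  # a selection with an unreachable cycle cannot be decoded
  lb <- build_lower_bound_model(ag)
  lb_sol <- solve_milp(lb)
  expect_error(extract_trail_and_alignment(ag, lb_sol), "disconnected")
})
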