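test_that("flow-projection lower bound reproduces known values", {
  same <- solve_ccted(single_edge("A"), single_edge("A", "p", "q"))
  expect_equal(same$value, 0)
  expect_false(same$is_ccted)  # open inputs: lower bound only

  diff <- solve_ccted(single_edge("A"), single_edge("C", "p", "q"))
  expect_equal(diff$value, 1)

  p <- make_two_triangle_pair()
  r <- solve_ccted(p$g1, p$g2)
  expect_equal(r$value, 0)
  expect_true(r$is_ccted)
  # the lower bound cannot exceed the exact distance
  expect_lte(r$value, brute_force_gted(p$g1, p$g2))
})

test_that("lower-bound ILP equals the brute-force cover distance", {
  for (s in 1:8) {
    pr <- random_closed_pair(s)
    expect_equal(solve_ccted(pr$g1, pr$g2)$value,
                 brute_force_ccted(pr$g1, pr$g2))
  }
  # identity and symmetry under unit costs
  g <- random_eulerian_graph(5, seed = 42)
  expect_equal(solve_ccted(g, g)$value, 0)
  pr <- random_closed_pair(3)
  expect_equal(solve_ccted(pr$g1, pr$g2)$value,
               solve_ccted(pr$g2, pr$g1)$value)
})

test_that("cover decoding yields matched closed trails summing to the objective", {
  p <- make_two_triangle_pair()
  r <- solve_ccted(p$g1, p$g2)
  cm <- decode_cover_matching(r$ag, r$solution)
  expect_equal(nrow(cm$pairs), 2)
  expect_equal(cm$pairs$cost, c(0, 0))
  expect_equal(cm$total, r$value)
  strs <- sort(c(cm$pairs$str1, cm$pairs$str2))
  # both sides decompose into the TTT cycle and a rotation of the GAA cycle
  expect_true(all(nchar(strs) == 3))

  for (s in 1:6) {
    pr <- random_closed_pair(s)
    r <- solve_ccted(pr$g1, pr$g2)
    cm <- decode_cover_matching(r$ag, r$solution)
    expect_equal(cm$total, r$value)
    # each side's trails jointly cover that graph's edge multiset
    for (side in 1:2) {
      g <- if (side == 1) pr$g1 else pr$g2
      strs <- cm$pairs[[paste0("str", side)]]
      lens <- sum(nchar(strs[!is.na(strs)]))
      expect_equal(lens, n_edges(g))
    }
    # a pair with an empty side costs the other trail's length
    eps1 <- is.na(cm$pairs$str1)
    expect_equal(cm$pairs$cost[eps1], nchar(cm$pairs$str2[eps1]))
    eps2 <- is.na(cm$pairs$str2)
    expect_equal(cm$pairs$cost[eps2], nchar(cm$pairs$str1[eps2]))
  }
})

test_that("boundary-matrix formulation matches the flow formulation", {
  p <- make_two_triangle_pair()
  ag <- build_alignment_graph(p$g1, p$g2)
  sm <- build_simplex_model(ag)
  # one triangle pair per orientation per unit pair
  expect_equal(sm$model$n_simplices, 2 * 36)
  expect_equal(sum(sm$model$x_init != 0), 12)
  expect_equal(solve_simplex_lb(p$g1, p$g2)$value, 0)

  # tiny case: counts from first principles
  g1 <- triangle(c("A", "A", "A"))
  g2 <- labeled_graph(data.frame(head = "z", tail = "z", label = "A"))
  ag2 <- build_alignment_graph(g1, g2)
  sm2 <- build_simplex_model(ag2)
  expect_equal(sm2$model$n_simplices, 2 * 3 * 1)
  expect_equal(sm2$model$n_edges, 3 * 1 + 3 * 1 + 3 * 1)

  for (s in 1:5) {
    pr <- random_closed_pair(s)
    expect_equal(solve_simplex_lb(pr$g1, pr$g2)$value,
                 solve_ccted(pr$g1, pr$g2)$value)
  }
  expect_error(build_simplex_model(augment_source_sink(ag)), "unaugmented")
  expect_error(
    build_simplex_model(build_alignment_graph(single_edge("A"),
                                              single_edge("A", "p", "q"))),
    "closed")
})

test_that("LP relaxation bounds the integer optimum from below", {
  p <- make_two_triangle_pair()
  expect_equal(solve_ccted(p$g1, p$g2, relax = TRUE)$value, 0)
  for (s in 1:4) {
    pr <- random_closed_pair(s)
    expect_lte(solve_ccted(pr$g1, pr$g2, relax = TRUE)$value,
               solve_ccted(pr$g1, pr$g2)$value + 1e-9)
  }
})
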