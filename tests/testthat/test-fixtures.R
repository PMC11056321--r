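test_that("two-triangle pair matches its published description", {
  p <- make_two_triangle_pair()
  for (g in p) {
    expect_length(g$nodes, 5)
    expect_equal(n_edges(g), 6)
    expect_equal(validate_eulerian_unidirectional(g)$kind, "closed")
  }
  expect_true(spell_trail(p$g1, eulerian_trail(p$g1, start = "c")) %in%
                c("TTTGAA", "GAATTT"))
  t2 <- enumerate_eulerian_trails(p$g2)
  expect_true("TTTAGA" %in% t2)
})

test_that("n-cycle generator produces valid closed graphs deterministically", {
  g <- make_ncycle_graph(3, c(3, 3, 4), seed = 5)
  expect_equal(n_edges(g), 10)
  expect_equal(validate_eulerian_unidirectional(g)$kind, "closed")

  # same seed, same graph; different seed, different labels
  g2 <- make_ncycle_graph(3, c(3, 3, 4), seed = 5)
  expect_identical(g$edges, g2$edges)
  g3 <- make_ncycle_graph(3, c(3, 3, 4), seed = 6)
  expect_false(identical(g$edges$label, g3$edges$label))

  # n = 2 with two 3-cycles is the two-triangle topology
  tt <- make_ncycle_graph(2, c(3, 3), seed = 1)
  expect_equal(n_edges(tt), 6)
  expect_length(tt$nodes, 5)

  # edge attachment duplicates a run of central edges
  ge <- make_ncycle_graph(2, c(4, 4), attachment = "edge", shared = 2,
                          seed = 2)
  expect_equal(n_edges(ge), 8)
  expect_equal(validate_eulerian_unidirectional(ge)$kind, "closed")
  expect_true(any(ge$edges$mult == 2))
})

test_that("Hamiltonian reduction obeys the size formulas", {
  path3 <- data.frame(from = c("v1", "v2"), to = c("v2", "v3"))
  inst <- make_hamiltonian_reduction(path3)
  expect_equal(n_edges(inst$closure), 32)
  expect_equal(nchar(inst$q), 32)
  expect_equal(n_edges(inst$cycle), 32)
  expect_equal(validate_eulerian_unidirectional(inst$closure)$kind, "closed")
  expect_equal(validate_eulerian_unidirectional(inst$cycle)$kind, "closed")
  expect_equal(spell_trail(inst$cycle, eulerian_trail(inst$cycle,
                                                      start = "y001")),
               inst$q)

  # size formulas on random simple digraphs
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2:4, 1)
    V <- sprintf("v%d", 1:n)
    all_e <- expand.grid(from = V, to = V, stringsAsFactors = FALSE)
    all_e <- all_e[all_e$from != all_e$to, ]
    keep <- all_e[sample(nrow(all_e), sample(seq_len(nrow(all_e)), 1)), ]
    inst <- make_hamiltonian_reduction(keep, vertices = V)
    m <- nrow(keep)
    expect_equal(n_edges(inst$closure), 2 * (4 * n + 2 * m))
    expect_equal(nchar(inst$q),
                 2 + 4 * (n - 1) + 2 * (2 * n - 1) + 4 * (m + 1))
    expect_equal(nchar(inst$q), n_edges(inst$closure))
  }

  expect_error(make_hamiltonian_reduction(
    data.frame(from = "a", to = "a")), "self-loops")
  expect_error(make_hamiltonian_reduction(
    data.frame(from = c("a", "a"), to = c("b", "b"))), "parallel")
})

test_that("reduction distance is zero exactly for Hamiltonian inputs", {
  # positive: the directed path on 3 vertices has a Hamiltonian path
  pos <- make_hamiltonian_reduction(
    data.frame(from = c("v1", "v2"), to = c("v2", "v3")))
  rp <- solve_gted_iterative(pos$closure, pos$cycle)
  expect_equal(rp$value, 0)
  expect_true(rp$optimal)

  # negative: two edges into a sink admit no Hamiltonian path
  neg <- make_hamiltonian_reduction(
    data.frame(from = c("v1", "v2"), to = c("v3", "v3")), vertices = paste0("v", 1:3))
  rn <- solve_gted_iterative(neg$closure, neg$cycle)
  expect_gte(rn$value, 1)
})

test_that("random sequence pairs follow the mutation model", {
  same <- random_sequence_pair(40, 0, seed = 9)
  expect_equal(same[1], same[2])

  full <- random_sequence_pair(40, 1, seed = 9)
  a <- strsplit(full[1], "")[[1]]
  b <- strsplit(full[2], "")[[1]]
  expect_true(all(a != b))
  expect_identical(full, random_sequence_pair(40, 1, seed = 9))
  expect_false(identical(full, random_sequence_pair(40, 1, seed = 10)))
})

test_that("random closed graphs validate and are reproducible", {
  for (s in 1:10) {
    g <- random_eulerian_graph(4 + s %% 3, seed = s)
    expect_equal(validate_eulerian_unidirectional(g)$kind, "closed")
  }
  expect_identical(random_eulerian_graph(5, seed = 2),
                   random_eulerian_graph(5, seed = 2))
})
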