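test_that("de Bruijn construction unrolls k-mers into labeled edges", {
  g <- build_debruijn("ACGT", k = 3)
  expect_setequal(g$nodes, c("AC", "CG", "GT"))
  expect_equal(n_edges(g), 2)
  expect_equal(g$edges$label[g$edges$head == "AC"], "G")
  expect_equal(g$edges$label[g$edges$head == "CG"], "T")

  # circular mode wraps: one edge per position, parallel k-mers merge
  g2 <- build_debruijn("TTTGAA", k = 2, circular = TRUE)
  expect_setequal(g2$nodes, c("T", "G", "A"))
  expect_equal(n_edges(g2), 6)
  tt <- g2$edges[g2$edges$head == "T" & g2$edges$tail == "T", ]
  expect_equal(tt$mult, 2L)
  expect_equal(tt$label, "T")

  expect_error(build_debruijn("AC", k = 4), "too short")
  # antiparallel (k-1)-mers are rejected with the offending pair
  expect_error(build_debruijn("ACA", k = 2), "antiparallel")
})

test_that("de Bruijn edge counts follow sequence length", {
  for (s in c("ACGTACGG", "TTTGAA", "AAGGTTCC")) {
    for (k in 2:4) {
      lin <- try(build_debruijn(s, k), silent = TRUE)
      if (!inherits(lin, "try-error")) {
        expect_equal(n_edges(lin), nchar(s) - k + 1)
      }
      circ <- try(build_debruijn(s, k, circular = TRUE), silent = TRUE)
      if (!inherits(circ, "try-error")) {
        expect_equal(n_edges(circ), nchar(s))
      }
    }
  }
})

test_that("Eulerian/unidirectional validation classifies trail kinds", {
  expect_equal(validate_eulerian_unidirectional(triangle(c("T", "T", "T")))$kind,
               "closed")

  k <- validate_eulerian_unidirectional(single_edge("A"))
  expect_equal(k$kind, "open")
  expect_equal(k$start, "u")
  expect_equal(k$end, "v")

  two_cycles <- labeled_graph(data.frame(
    head = c("a", "x"), tail = c("a", "x"), label = c("A", "G")))
  expect_error(validate_eulerian_unidirectional(two_cycles), "not connected")

  anti <- labeled_graph(data.frame(head = c("a", "b", "b"),
                                   tail = c("b", "a", "c"),
                                   label = c("A", "C", "G")))
  expect_error(validate_eulerian_unidirectional(anti), "antiparallel")

  star <- labeled_graph(data.frame(head = c("a", "a"), tail = c("b", "c"),
                                   label = c("A", "C")))
  expect_error(validate_eulerian_unidirectional(star), "degree condition")
})

test_that("parallel-edge merging groups by head, tail and label", {
  loops <- labeled_graph(data.frame(head = c("T", "T"), tail = c("T", "T"),
                                    label = c("T", "T")))
  expect_equal(nrow(loops$edges), 1)
  expect_equal(loops$edges$mult, 2L)

  two_labels <- labeled_graph(data.frame(head = c("u", "u"),
                                         tail = c("v", "v"),
                                         label = c("A", "C")))
  expect_equal(nrow(two_labels$edges), 2)
  expect_equal(two_labels$edges$mult, c(1L, 1L))

  empty <- labeled_graph(data.frame())
  expect_equal(nrow(empty$edges), 0)

  # round trip: expanding multiplicities and re-merging is idempotent
  g <- build_debruijn("TTTGAATTT", 2, circular = TRUE)
  re <- labeled_graph(expand_edges(g)[, c("head", "tail", "label")])
  expect_identical(re$edges, g$edges)
  expect_identical(merge_parallel_edges(g)$edges, g$edges)
})

test_that("deterministic Eulerian trails spell the source sequence", {
  for (s in c("TTTGAA", "TTGGAA", "CCCTGG")) {
    g <- build_debruijn(s, 2, circular = TRUE)
    spelled <- spell_trail(g, eulerian_trail(g))
    rotations <- vapply(seq_len(nchar(s)), function(i) {
      paste0(substr(s, i, nchar(s)), substr(s, 1, i - 1))
    }, "")
    expect_true(spelled %in% rotations)
    # trail is reproducible
    expect_identical(eulerian_trail(g), eulerian_trail(g))
  }
  # open trail spells the k-1 suffix concatenation exactly
  g <- build_debruijn("ACGTT", 3)
  expect_equal(spell_trail(g, eulerian_trail(g)), "GTT")
})
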