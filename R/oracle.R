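#' Edit distance between two strings
#'
#' Standard dynamic-programming edit distance under a [cost_model()]:
#' insertions and deletions cost `indel`, substitutions `mismatch`, and
#' aligned equal characters `match`. With the default unit costs this is the
#' Levenshtein distance. Serves as the independent reference for the
#' graph-based computations.
#'
#' @param s1,s2 Character scalars.
#' @param costs A [cost_model()].
#' @return Numeric distance.
#' @export
levenshtein <- function(s1, s2, costs = cost_model()) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  prev <- (0:m) * costs$indel
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i * costs$indel
    for (j in seq_len(m)) {
      sub <- prev[j] + if (a[i] == b[j]) costs$match else costs$mismatch
      cur[j + 1] <- min(sub, prev[j + 1] + costs$indel, cur[j] + costs$indel)
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Rotation-free edit distance between cyclic strings
#'
#' Minimum of [levenshtein()] over all rotations of both strings. This is the
#' appropriate distance between strings spelled by closed trails, which fix
#' no starting point.
#'
#' @inheritParams levenshtein
#' @return Numeric distance.
#' @export
cyclic_edit_distance <- function(s1, s2, costs = cost_model()) {
  rots <- function(s) {
    n <- nchar(s)
    if (n <= 1) return(s)
    unique(vapply(seq_len(n), function(i) {
      paste0(substr(s, i, n), substr(s, 1, i - 1))
    }, ""))
  }
  best <- Inf
  for (r1 in rots(s1)) {
    for (r2 in rots(s2)) {
      best <- min(best, levenshtein(r1, r2, costs))
    }
  }
  best
}

#' Enumerate all Eulerian trails of a small graph
#'
#' Exhaustive backtracking over edge orderings; closed graphs are enumerated
#' from every start node. Intended for graphs with at most ~8 edges. The
#' search counts extended partial trails and aborts at `limit`.
#'
#' @param g A valid `labeled_graph`.
#' @param limit Maximum number of partial states explored.
#' @return Sorted character vector of the distinct spelled strings.
#' @export
enumerate_eulerian_trails <- function(g, limit = 1e6) {
  kind <- validate_eulerian_unidirectional(g)
  units <- expand_edges(g)
  n <- nrow(units)
  out_by <- split(seq_len(n), units$head)
  states <- 0L
  results <- new.env(parent = emptyenv())
  recurse <- function(cur, used, k, labels) {
    states <<- states + 1L
    if (states > limit) stop("enumeration limit exceeded")
    if (k == n) {
      assign(paste(labels, collapse = ""), TRUE, envir = results)
      return(invisible())
    }
    for (i in out_by[[cur]]) {
      if (!used[i]) {
        used[i] <- TRUE
        recurse(units$tail[i], used, k + 1L, c(labels, units$label[i]))
        used[i] <- FALSE
      }
    }
  }
  starts <- if (kind$kind == "open") kind$start else
    unique(units$head)
  for (s in starts) recurse(s, logical(n), 0L, character(0))
  sort(ls(results))
}

#' Brute-force traversal edit distance
#'
#' Enumerates every Eulerian trail of both graphs and takes the minimum
#' pairwise [levenshtein()] distance of the spelled strings. Exact reference
#' for small instances.
#'
#' @param g1,g2 Valid `labeled_graph` inputs.
#' @param costs A [cost_model()].
#' @param limit Enumeration state limit per graph.
#' @return Numeric distance.
#' @export
brute_force_gted <- function(g1, g2, costs = cost_model(), limit = 1e6) {
  t1 <- enumerate_eulerian_trails(g1, limit)
  t2 <- enumerate_eulerian_trails(g2, limit)
  best <- Inf
  for (a in t1) for (b in t2) {
    best <- min(best, levenshtein(a, b, costs))
  }
  best
}

# enumerate all decompositions of a closed graph into edge-disjoint closed
# trails; returns a list of covers, each a character vector of trail strings
enumerate_closed_trail_covers <- function(g, limit = 1e6) {
  units <- expand_edges(g)
  n <- nrow(units)
  covers <- list()
  states <- 0L
  # enumerate closed trails that start with the given unit, then recurse on
  # the remainder; anchoring each trail at the smallest remaining unit makes
  # every cover appear at least once without enumerating rotations
  recurse_cover <- function(used, acc) {
    rem <- which(!used)
    if (length(rem) == 0) {
      covers[[length(covers) + 1L]] <<- acc
      return(invisible())
    }
    u0 <- rem[1]
    start <- units$head[u0]
    used[u0] <- TRUE
    extend <- function(cur, used, labels) {
      states <<- states + 1L
      if (states > limit) stop("enumeration limit exceeded")
      if (cur == start) {
        recurse_cover(used, c(acc, paste(labels, collapse = "")))
        # also try continuing through the start node
      }
      for (i in which(!used & units$head == cur)) {
        used[i] <- TRUE
        extend(units$tail[i], used, c(labels, units$label[i]))
        used[i] <- FALSE
      }
    }
    extend(units$tail[u0], used, units$label[u0])
  }
  recurse_cover(logical(n), character(0))
  covers
}

#' Brute-force closed-trail cover traversal edit distance
#'
#' Exhaustively enumerates all decompositions of each (closed) input into
#' edge-disjoint closed trails, and for every pair of covers the minimum-cost
#' matching of their trails: matched trails cost their rotation-free
#' [cyclic_edit_distance()], and a trail matched with the empty item costs
#' its length times the indel cost. The overall minimum is the reference
#' value for [solve_ccted()] on small instances.
#'
#' @inheritParams brute_force_gted
#' @return Numeric distance.
#' @export
brute_force_ccted <- function(g1, g2, costs = cost_model(), limit = 1e6) {
  k1 <- validate_eulerian_unidirectional(g1)
  k2 <- validate_eulerian_unidirectional(g2)
  if (k1$kind != "closed" || k2$kind != "closed") {
    stop("closed-trail cover distance requires closed inputs")
  }
  cov1 <- enumerate_closed_trail_covers(g1, limit)
  cov2 <- enumerate_closed_trail_covers(g2, limit)
  # min-cost matching by recursion over the smaller side with memo-free
  # branch and bound (covers are tiny)
  match_cost <- function(a, b) {
    if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
    pad <- length(b) - length(a)
    items <- c(a, rep(NA_character_, pad))
    best <- Inf
    assign_next <- function(i, free, acc) {
      if (acc >= best) return(invisible())
      if (i > length(items)) { best <<- acc; return(invisible()) }
      for (j in free) {
        cost <- if (is.na(items[i])) nchar(b[j]) * costs$indel else
          cyclic_edit_distance(items[i], b[j], costs)
        assign_next(i + 1L, setdiff(free, j), acc + cost)
      }
    }
    assign_next(1L, seq_along(b), 0)
    best
  }
  best <- Inf
  for (c1 in cov1) for (c2 in cov2) {
    best <- min(best, match_cost(c1, c2))
  }
  best
}
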