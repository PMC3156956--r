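# Shared fixtures and independent oracles, built in code.

worked_P <- function() make_genome(list(c("+a", "+b"), c("+c", "+e", "-d")))
worked_Q <- function() make_genome(list(c("+a", "+b", "-e", "+c", "+d")))

# Independent cycle-structure oracle: superimpose the two matchings as an
# igraph multigraph and classify connected components by size.  A shared
# adjacency gives a 2-vertex component (trivial cycle).
oracle_bc <- function(P, Q) {
  ed <- rbind(adjacencies(P), adjacencies(Q))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$csize > 2]
  list(b = sum(sizes) / 2, c = length(sizes))
}

# Enumerate all perfect matchings on extremities 1..2m: every matching is a
# valid circular genome.
all_matchings <- function(m) {
  verts <- seq_len(2L * m)
  rec <- function(vs) {
    if (length(vs) == 0L) return(list(integer(0)))
    a <- vs[1L]
    out <- list()
    for (b in vs[-1L]) {
      rest <- setdiff(vs, c(a, b))
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(a, b, tail)
    }
    out
  }
  lapply(rec(verts), function(p) {
    adj <- integer(2L * m)
    for (i in seq(1L, length(p), by = 2L)) {
      adj[p[i]] <- p[i + 1L]
      adj[p[i + 1L]] <- p[i]
    }
    new_genome_for_test(adj, as.character(seq_len(m)))
  })
}

new_genome_for_test <- function(adj, labels) {
  structure(list(adj = as.integer(adj), labels = labels), class = "genome")
}

genome_key <- function(g) paste(g$adj, collapse = ",")

# All genomes reachable by one 2-break (both reconnections of every
# adjacency pair), used by the BFS distance oracle.
two_break_neighbours <- function(g) {
  am <- adjacencies(g)
  n <- nrow(am)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    u <- am[i, 1L]; v <- am[i, 2L]; x <- am[j, 1L]; y <- am[j, 2L]
    for (joined in list(list(c(u, x), c(v, y)), list(c(u, y), c(v, x)))) {
      adj <- g$adj
      adj[joined[[1L]][1L]] <- joined[[1L]][2L]
      adj[joined[[1L]][2L]] <- joined[[1L]][1L]
      adj[joined[[2L]][1L]] <- joined[[2L]][2L]
      adj[joined[[2L]][2L]] <- joined[[2L]][1L]
      out[[length(out) + 1L]] <- new_genome_for_test(adj, g$labels)
    }
  }
  out
}

# BFS distance matrix over the 2-break move graph on all genomes with m
# blocks; rows/cols indexed like all_matchings(m).
bfs_distance_matrix <- function(genomes) {
  keys <- vapply(genomes, genome_key, "")
  nbrs <- lapply(genomes, function(g)
    match(vapply(two_break_neighbours(g), genome_key, ""), keys))
  n <- length(genomes)
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in nbrs[[v]]) if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        queue <- c(queue, u)
      }
    }
    D[s, ] <- dist
  }
  D
}

scenario_row_as_two_break <- function(scen, i) {
  structure(list(broken1 = scen[i, 1:2], broken2 = scen[i, 3:4],
                 joined1 = scen[i, 5:6], joined2 = scen[i, 7:8]),
            class = "two_break")
}

apply_scenario <- function(g, scen) {
  for (i in seq_len(nrow(scen)))
    g <- apply_two_break(g, scenario_row_as_two_break(scen, i))
  g
}

# Exact FBM expectation for the inter-reuse of two branches of t1 and t2
# 2-breaks on n fragile sites: per-step vertex use is an independent
# Bernoulli(2/n) event, without the exponential approximation.
exact_fbm_inter <- function(n, t1, t2) {
  2 * n * (1 - (1 - 2 / n)^t1) * (1 - (1 - 2 / n)^t2)
}
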