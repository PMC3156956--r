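#' Breakpoint graph of two genomes
#'
#' The breakpoint graph G(P, Q) superimposes the adjacency matchings of two
#' genomes over the same block set: "black" edges from P and "red" edges
#' from Q on the 2m extremity vertices.  Black and red edges form
#' alternating black-red cycles.  A cycle with exactly two edges (a black
#' edge parallel to a red edge) is *trivial* and corresponds to an adjacency
#' shared by P and Q.  Vertices on non-trivial cycles are *breakpoints*;
#' they delimit b(P,Q) synteny blocks of the pair, where b equals the number
#' of black edges on non-trivial cycles.
#'
#' Each cycle is stored as its vertex sequence `v1, v2, ..., v2k` in which
#' `(v1,v2), (v3,v4), ...` are black (P) edges and `(v2,v3), ..., (v2k,v1)`
#' are red (Q) edges; the cycle length |C| equals 2k.
#'
#' @param P,Q `genome` objects over the same synteny blocks.
#' @return An object of class `"breakpoint_graph"`: a list with `cycles`
#'   (list of integer vertex sequences), `trivial` (logical per cycle), `b`,
#'   `c` (non-trivial cycle count), `n_trivial`, `vertex_cycle` (vertex to
#'   cycle index lookup) and `labels`.
#' @examples
#' P <- make_genome(list(c("+a", "+b"), c("+c", "+e", "-d")))
#' Q <- make_genome(list(c("+a", "+b", "-e", "+c", "+d")))
#' bg <- breakpoint_graph(P, Q)
#' bg$b                       # 4 synteny blocks
#' bg$c                       # 2 non-trivial cycles
#' two_break_distance(P, Q)   # 4 - 2 = 2
#' @export
breakpoint_graph <- function(P, Q) {
  check_same_blocks(P, Q)
  adjP <- P$adj
  adjQ <- Q$adj
  nv <- length(adjP)
  visited <- logical(nv)
  cycles <- list()
  vertex_cycle <- integer(nv)
  for (v in seq_len(nv)) {
    if (visited[v]) next
    seqv <- integer(0)
    cur <- v
    repeat {
      nxt <- adjP[cur]          # black edge
      seqv <- c(seqv, cur, nxt)
      visited[cur] <- TRUE
      visited[nxt] <- TRUE
      cur <- adjQ[nxt]          # red edge
      if (cur == v) break
    }
    cycles[[length(cycles) + 1L]] <- seqv
    vertex_cycle[seqv] <- length(cycles)
  }
  triv <- lengths(cycles) == 2L
  structure(list(cycles = cycles,
                 trivial = triv,
                 b = sum(lengths(cycles)[!triv]) %/% 2L,
                 c = sum(!triv),
                 n_trivial = sum(triv),
                 vertex_cycle = vertex_cycle,
                 labels = P$labels),
            class = "breakpoint_graph")
}

#' @export
print.breakpoint_graph <- function(x, ...) {
  cat("Breakpoint graph: b =", x$b, ", c =", x$c,
      "non-trivial cycles,", x$n_trivial, "trivial\n")
  invisible(x)
}

#' Breakpoint vertices of a breakpoint graph
#'
#' Vertices lying on non-trivial cycles, i.e. the endpoints of the
#' (P,Q)-synteny blocks.
#'
#' @param bg A `breakpoint_graph`.
#' @return Integer extremity ids.
#' @export
breakpoint_vertices <- function(bg) {
  unlist(bg$cycles[!bg$trivial], use.names = FALSE)
}

#' 2-break distance between circular genomes
#'
#' The minimum number of 2-breaks transforming P into Q equals
#' b(P,Q) - c(P,Q): the number of synteny blocks minus the number of
#' non-trivial black-red cycles in the breakpoint graph.
#'
#' @param P,Q `genome` objects over the same block set.
#' @return Non-negative integer distance.
#' @export
two_break_distance <- function(P, Q) {
  bg <- breakpoint_graph(P, Q)
  bg$b - bg$c
}

#' Enumerate the 2-breaks that split a black-red cycle
#'
#' For a non-trivial cycle C with |C| edges (|C|/2 black edges) there are
#' |C|(|C|-2)/8 2-breaks acting on two black edges of C whose reconnection
#' splits C into two cycles, thereby increasing the cycle count by one and
#' decreasing the 2-break distance by one.  For every unordered pair of
#' black edges exactly one of its two reconnections is splitting, and that
#' one is returned.
#'
#' @param cycle A cycle, either an integer vertex sequence as stored in a
#'   [breakpoint_graph()] (black edges at positions (1,2), (3,4), ...) or a
#'   single-cycle `breakpoint_graph`.
#' @return A list of `two_break` objects (empty for a trivial cycle).
#' @examples
#' P <- make_genome(list(c(1, 2, 3)))
#' Q <- make_genome(list(c(1, -2, -3)))
#' bg <- breakpoint_graph(P, Q)
#' length(splitting_two_breaks(bg$cycles[[1]]))
#' @export
splitting_two_breaks <- function(cycle) {
  if (inherits(cycle, "breakpoint_graph")) {
    nt <- cycle$cycles[!cycle$trivial]
    if (length(nt) != 1L)
      stop("pass a single cycle (vertex sequence) or a one-cycle graph",
           call. = FALSE)
    cycle <- nt[[1L]]
  }
  v <- as.integer(cycle)
  k <- length(v) %/% 2L
  if (k < 2L) return(list())
  out <- vector("list", k * (k - 1L) %/% 2L)
  idx <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      idx <- idx + 1L
      out[[idx]] <- structure(
        list(broken1 = c(v[2L * i - 1L], v[2L * i]),
             broken2 = c(v[2L * j - 1L], v[2L * j]),
             joined1 = c(v[2L * i], v[2L * j - 1L]),
             joined2 = c(v[2L * j], v[2L * i - 1L])),
        class = "two_break")
    }
  }
  out
}

# Split the vertex sequence of a cycle at black edges i < j (1-based black
# edge indices); returns the two resulting cycle sequences, each starting
# with its new black edge.
split_cycle_at <- function(v, i, j) {
  a <- c(v[2L * j - 1L], v[(2L * i):(2L * j - 2L)])
  head_part <- if (i > 1L) v[seq_len(2L * i - 2L)] else integer(0)
  b <- c(v[2L * i - 1L], v[(2L * j):length(v)], head_part)
  list(a, b)
}
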