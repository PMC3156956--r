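#' 2-break rearrangement operations
#'
#' A 2-break replaces two adjacencies (u,v) and (x,y) of a genome by one of
#' the two possible reconnections on the same four extremities: either
#' {(u,x),(v,y)} or {(u,y),(v,x)}.  For circular chromosomes 2-breaks
#' subsume reversals, fusions, fissions and translocations (the DCJ
#' operation).  A 2-break *uses* its four extremities u, v, x, y.
#'
#' @param broken1,broken2 The two adjacencies to cut, each a length-2 vector
#'   of extremity ids (or labels, with `g` supplied).
#' @param joined1,joined2 The two replacement adjacencies; together they
#'   must cover exactly the four broken extremities and differ from the
#'   broken pairing.
#' @param g Optional `genome` used to resolve character extremity labels
#'   such as `"ah"`.
#' @return An object of class `"two_break"` with fields `broken1`,
#'   `broken2`, `joined1`, `joined2`.
#' @examples
#' P <- make_genome(list(c("+a", "+b"), c("+c", "+e", "-d")))
#' tb <- two_break(c("ch", "et"), c("eh", "dh"), c("ch", "dh"), c("et", "eh"),
#'                 g = P)
#' apply_two_break(P, tb)
#' @export
two_break <- function(broken1, broken2, joined1, joined2, g = NULL) {
  conv <- function(p) {
    if (is.character(p)) {
      if (is.null(g)) stop("supply 'g' to resolve extremity labels", call. = FALSE)
      p <- extremity_id(g, p)
    }
    as.integer(p)
  }
  b1 <- conv(broken1); b2 <- conv(broken2)
  j1 <- conv(joined1); j2 <- conv(joined2)
  verts <- c(b1, b2)
  if (length(unique(verts)) != 4L)
    stop("a 2-break must act on two disjoint adjacencies (4 distinct extremities)",
         call. = FALSE)
  if (!setequal(c(j1, j2), verts))
    stop("joined adjacencies must cover exactly the four broken extremities",
         call. = FALSE)
  canon <- function(p) sort(p)
  if (setequal(list(canon(j1)), list(canon(b1))) ||
      setequal(list(canon(j1)), list(canon(b2))))
    stop("joined adjacencies must differ from the broken ones", call. = FALSE)
  structure(list(broken1 = b1, broken2 = b2, joined1 = j1, joined2 = j2),
            class = "two_break")
}

#' @export
print.two_break <- function(x, ...) {
  cat("2-break: break (", paste(x$broken1, collapse = ","), ") (",
      paste(x$broken2, collapse = ","), ") -> join (",
      paste(x$joined1, collapse = ","), ") (",
      paste(x$joined2, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Vertices used by a 2-break
#' @param tb A `two_break`.
#' @return The four extremity ids.
#' @export
used_vertices <- function(tb) c(tb$broken1, tb$broken2)

#' Apply a 2-break to a genome
#'
#' Returns a new genome; the input is never modified, so many genome
#' snapshots along a scenario can coexist.
#'
#' @param g A `genome`.
#' @param tb A `two_break` whose broken adjacencies are present in `g`.
#' @return The rearranged `genome`.
#' @export
apply_two_break <- function(g, tb) {
  adj <- g$adj
  if (adj[tb$broken1[1L]] != tb$broken1[2L] ||
      adj[tb$broken2[1L]] != tb$broken2[2L])
    stop("stale 2-break: a broken adjacency is not present in the genome",
         call. = FALSE)
  adj[tb$joined1[1L]] <- tb$joined1[2L]
  adj[tb$joined1[2L]] <- tb$joined1[1L]
  adj[tb$joined2[1L]] <- tb$joined2[2L]
  adj[tb$joined2[2L]] <- tb$joined2[1L]
  new_genome(adj, g$labels)
}

#' Invert a 2-break
#'
#' Applying `inverse_two_break(tb)` after `tb` restores the original genome.
#'
#' @param tb A `two_break`.
#' @return The inverse `two_break`.
#' @export
inverse_two_break <- function(tb) {
  structure(list(broken1 = tb$joined1, broken2 = tb$joined2,
                 joined1 = tb$broken1, joined2 = tb$broken2),
            class = "two_break")
}
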