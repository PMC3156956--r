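# Normalize a scenario (matrix from simulate_tree / sample_shortest_scenario,
# or a list of two_break) to its per-step used-vertex matrix (rows = steps).
scenario_vertex_matrix <- function(scenario) {
  if (is.matrix(scenario)) return(scenario[, 1:4, drop = FALSE])
  if (inherits(scenario, "two_break")) scenario <- list(scenario)
  if (is.list(scenario))
    return(do.call(rbind, c(lapply(scenario, used_vertices),
                            list(matrix(0L, 0L, 4L)))))
  stop("not a scenario: expected a scenario matrix or list of two_break",
       call. = FALSE)
}

#' Intra-branch breakpoint reuse of a scenario
#'
#' A vertex (block extremity) is intra-reused on a branch when at least two
#' distinct 2-breaks of the branch scenario use it.  `br` counts the
#' intra-reused vertices; the weighted reuse `BR` sums max(0, use(v) - 1)
#' over vertices, so `BR = br` when no vertex is used more than twice.
#'
#' @param scenario An ordered scenario: the matrix stored in a
#'   [simulate_tree()] result, a [sample_shortest_scenario()] result, or a
#'   list of `two_break`s.
#' @return Named integer vector `c(br = , BR = )`.
#' @export
intra_reuse <- function(scenario) {
  vm <- scenario_vertex_matrix(scenario)
  cnt <- tabulate(vm)
  c(br = sum(cnt >= 2L), BR = sum(pmax(cnt - 1L, 0L)))
}

#' Inter-branch breakpoint reuse between two scenarios
#'
#' The number of vertices used by at least one 2-break in each of two
#' branch scenarios; each vertex counts once regardless of multiplicity.
#'
#' @param scenario1,scenario2 Scenarios from two distinct branches (see
#'   [intra_reuse()] for accepted forms).
#' @return Non-negative integer count.
#' @export
inter_reuse <- function(scenario1, scenario2) {
  v1 <- scenario_vertex_matrix(scenario1)
  v2 <- scenario_vertex_matrix(scenario2)
  length(intersect(unique(as.vector(v1)), unique(as.vector(v2))))
}

#' Breakpoint-graph lower bound on intra-branch reuse
#'
#' For a branch with endpoint genomes P and Q, `4 d(P,Q) - 2 b(P,Q)`
#' (clamped at 0) bounds the weighted intra-reuse BR from below: a shortest
#' scenario uses 4d extremity slots but only 2b distinct breakpoints exist.
#'
#' @param P,Q `genome`s at the two ends of the branch.
#' @return Non-negative integer.
#' @export
bound_intra <- function(P, Q) {
  bg <- breakpoint_graph(P, Q)
  max(0L, 4L * (bg$b - bg$c) - 2L * bg$b)
}

#' Breakpoint-graph lower bound on inter-branch reuse
#'
#' The number of vertices shared between the non-trivial cycles of the two
#' branches' breakpoint graphs.  It equals the actual inter-reuse whenever
#' both branch scenarios are shortest.
#'
#' @param bg1,bg2 `breakpoint_graph`s of the two branches.
#' @return Non-negative integer.
#' @export
bound_inter <- function(bg1, bg2) {
  length(intersect(breakpoint_vertices(bg1), breakpoint_vertices(bg2)))
}

#' Expected inter- and intra-reuse under FBM
#'
#' With n fragile sites, a random 2-break uses a given fragile vertex with
#' probability 2/n, so t1 and t2 independent 2-breaks on two branches
#' inter-reuse an expected `2n (1 - exp(-2 t1/n)) (1 - exp(-2 t2/n))`
#' vertices.  The expected intra-reuse on a branch of t 2-breaks is
#' `2n (1 - exp(-2t/n) - (2t/n) exp(-2(t-1)/n))`; this approximation can
#' dip marginally below zero for small t and is clamped at 0.
#'
#' @param n Number of fragile regions.
#' @param t1,t2,t Branch lengths in 2-breaks (`t >= 1` for `expected_intra`).
#' @return Expected number of reused vertices.
#' @examples
#' expected_inter(900, 100, 100)  # about 71.5
#' @export
expected_inter <- function(n, t1, t2) {
  stopifnot(n > 0)
  2 * n * (1 - exp(-2 * t1 / n)) * (1 - exp(-2 * t2 / n))
}

#' @rdname expected_inter
#' @export
expected_intra <- function(n, t) {
  stopifnot(n > 0, t >= 1)
  pmax(0, 2 * n * (1 - exp(-2 * t / n) - (2 * t / n) * exp(-2 * (t - 1) / n)))
}

#' Scaled breakpoint reuse
#'
#' Observed reuse divided by its FBM expectation; values near 1 indicate
#' FBM-like behaviour.
#'
#' @param observed Observed reuse count.
#' @param expected Expected reuse (> 0).
#' @return Ratio.
#' @export
scaled_reuse <- function(observed, expected) {
  if (any(expected <= 0)) stop("undefined scale: expected reuse must be > 0",
                               call. = FALSE)
  observed / expected
}

#' Breakpoint-reuse table over all branch pairs of a tree
#'
#' Assembles the symmetric branch-by-branch table: diagonal cells carry the
#' intra-reuse of each branch (`br`, with `BR` and the bound
#' `4d - 2b` alongside), off-diagonal cells the inter-reuse of the pair and
#' its breakpoint-graph bound, plus the red/green/yellow separation class
#' of the pair.  With a `scenario_tree` both actual and bound values are
#' available; from genomes alone (real data) only the bounds are.
#'
#' @param x A `scenario_tree`, or a `rearr_tree` (then supply `genomes`).
#' @param genomes Named list of `genome`s at all tree nodes; required when
#'   `x` is a `rearr_tree`.
#' @return An object of class `"reuse_table"`: branch names, matrices
#'   `actual` (NA when scenarios unknown) and `bound`, diagonal vectors
#'   `br`, `BR`, `bound_diag`, the class matrix, per-branch `shortest`
#'   flags, and `has_scenarios`.
#' @examples
#' st <- simulate_tree(simulation_config(m = 300, n = 150, x = 0,
#'                                       chromosomes = 5, seed = 7))
#' rt <- reuse_table(st)
#' rt$actual["M+", "R+"]
#' @export
reuse_table <- function(x, genomes = NULL) {
  if (inherits(x, "scenario_tree")) {
    tr <- x$tree
    genomes <- x$genomes
    scenarios <- x$scenarios
    from <- x$from; to <- x$to
    has_scen <- TRUE
  } else if (inherits(x, "rearr_tree")) {
    if (is.null(genomes)) stop("supply node genomes with a bare tree",
                               call. = FALSE)
    tr <- x
    scenarios <- NULL
    from <- structure(tr$edges$parent, names = tr$edges$name)
    to <- structure(tr$edges$child, names = tr$edges$name)
    has_scen <- FALSE
  } else stop("'x' must be a scenario_tree or rearr_tree", call. = FALSE)
  nm <- tr$edges$name
  k <- length(nm)
  bgs <- lapply(nm, function(e) breakpoint_graph(genomes[[from[e]]],
                                                 genomes[[to[e]]]))
  names(bgs) <- nm
  actual <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  bound <- matrix(0, k, k, dimnames = list(nm, nm))
  classes <- matrix(NA_character_, k, k, dimnames = list(nm, nm))
  br <- BR <- bound_diag <- stats::setNames(numeric(k), nm)
  shortest <- stats::setNames(logical(k), nm)
  for (i in seq_len(k)) {
    bound_diag[i] <- max(0, 4 * (bgs[[i]]$b - bgs[[i]]$c) - 2 * bgs[[i]]$b)
    bound[i, i] <- bound_diag[i]
    if (has_scen) {
      ir <- intra_reuse(scenarios[[nm[i]]])
      br[i] <- ir["br"]; BR[i] <- ir["BR"]
      actual[i, i] <- br[i]
      shortest[i] <- nrow(scenarios[[nm[i]]]) == bgs[[i]]$b - bgs[[i]]$c
    }
    for (j in seq_len(k)) {
      if (i == j) next
      bound[i, j] <- bound_inter(bgs[[i]], bgs[[j]])
      classes[i, j] <- branch_pair_class(tr, nm[i], nm[j])
      if (has_scen)
        actual[i, j] <- inter_reuse(scenarios[[nm[i]]], scenarios[[nm[j]]])
    }
  }
  structure(list(branches = nm, actual = actual, bound = bound, br = br,
                 BR = BR, bound_diag = bound_diag, classes = classes,
                 shortest = shortest, has_scenarios = has_scen, tree = tr),
            class = "reuse_table")
}

#' @export
print.reuse_table <- function(x, ...) {
  k <- length(x$branches)
  cells <- matrix("", k, k, dimnames = list(x$branches, x$branches))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cells[i, j] <- if (x$has_scenarios)
      paste0(x$actual[i, j], ":", x$bound[i, j]) else as.character(x$bound[i, j])
  }
  cat("Breakpoint reuse table (",
      if (x$has_scenarios) "actual:bound" else "bounds only", ")\n", sep = "")
  print(as.data.frame(cells))
  invisible(x)
}

#' Mean inter-reuse by branch-pair class
#'
#' @param rt A `reuse_table`.
#' @param what `"actual"` or `"bound"` cells.
#' @return Named numeric vector with the mean inter-reuse of `red`, `green`
#'   and `yellow` branch pairs (and `other` when present).
#' @export
class_means <- function(rt, what = c("actual", "bound")) {
  what <- match.arg(what)
  M <- rt[[what]]
  up <- upper.tri(M)
  tapply(M[up], factor(rt$classes[up],
                       levels = c("red", "green", "yellow", "other")),
         mean)[c("red", "green", "yellow")]
}

#' Export a reuse table
#'
#' Writes the branch-by-branch table as TSV (cells `"actual:bound"`, or the
#' bound alone for real data) and/or as JSON including the class colours.
#'
#' @param rt A `reuse_table`.
#' @param tsv,json Output paths (either may be `NULL`).
#' @return Invisibly, the list of paths written.
#' @export
write_reuse_table <- function(rt, tsv = NULL, json = NULL) {
  k <- length(rt$branches)
  if (!is.null(tsv)) {
    cells <- matrix("", k, k, dimnames = list(rt$branches, rt$branches))
    for (i in seq_len(k)) for (j in seq_len(k))
      cells[i, j] <- if (rt$has_scenarios)
        paste0(rt$actual[i, j], ":", rt$bound[i, j])
      else as.character(rt$bound[i, j])
    utils::write.table(cells, tsv, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(branches = rt$branches, actual = rt$actual, bound = rt$bound,
           br = as.list(rt$br), BR = as.list(rt$BR),
           classes = rt$classes, shortest = as.list(rt$shortest)),
      json, auto_unbox = TRUE, na = "null", pretty = TRUE)
  }
  invisible(list(tsv = tsv, json = json))
}
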