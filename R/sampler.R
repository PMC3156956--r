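#' Sample a shortest 2-break scenario between two genomes
#'
#' Iteratively selects a non-trivial cycle C of the current breakpoint
#' graph with probability proportional to |C|/2 - 1 (the number of 2-breaks
#' needed to resolve C; the proportionality constant is the remaining
#' distance), then applies one of the |C|(|C|-2)/8 splitting 2-breaks of C
#' chosen uniformly.  Every step increases the cycle count by one, so the
#' sampled scenario has length exactly d(P,Q) = b - c and transforms P
#' into Q.
#'
#' This is a specific proposal distribution over shortest scenarios, not
#' the uniform distribution on them.
#'
#' @param P,Q `genome`s over the same block set.
#' @param seed Optional integer seed.
#' @param bg Optional precomputed `breakpoint_graph(P, Q)` (an
#'   optimization when sampling repeatedly for the same pair).
#' @return A scenario matrix (class `"scenario"`) with one row per 2-break
#'   and columns `u, v, x, y` (broken adjacencies (u,v), (x,y)) and
#'   `j1a, j1b, j2a, j2b` (joined); zero rows when `P == Q`.
#' @examples
#' P <- make_genome(list(c("+a", "+b"), c("+c", "+e", "-d")))
#' Q <- make_genome(list(c("+a", "+b", "-e", "+c", "+d")))
#' nrow(sample_shortest_scenario(P, Q, seed = 1))  # d(P,Q) = 2
#' @export
sample_shortest_scenario <- function(P, Q, seed = NULL, bg = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bg)) bg <- breakpoint_graph(P, Q)
  scen <- sample_scenario_from_cycles(bg$cycles[!bg$trivial])
  colnames(scen) <- c("u", "v", "x", "y", "j1a", "j1b", "j2a", "j2b")
  structure(scen, class = c("scenario", class(scen)))
}

# Core sampler over a list of non-trivial cycle vertex sequences.
sample_scenario_from_cycles <- function(cycles) {
  w <- lengths(cycles) %/% 2L - 1L
  d <- sum(w)
  scen <- matrix(0L, d, 8L)
  step <- 0L
  while (length(cycles) > 0L) {
    ci <- if (length(cycles) == 1L) 1L
          else sample.int(length(cycles), 1L, prob = w)
    v <- cycles[[ci]]
    k <- length(v) %/% 2L
    pr <- sort(sample.int(k, 2L))  # uniform unordered pair of black edges
    i <- pr[1L]; j <- pr[2L]
    step <- step + 1L
    scen[step, ] <- c(v[2L * i - 1L], v[2L * i], v[2L * j - 1L], v[2L * j],
                      v[2L * i], v[2L * j - 1L], v[2L * j], v[2L * i - 1L])
    parts <- split_cycle_at(v, i, j)
    keep <- lengths(parts) > 2L
    cycles[[ci]] <- NULL
    w <- w[-ci]
    if (any(keep)) {
      cycles <- c(cycles, parts[keep])
      w <- c(w, lengths(parts[keep]) %/% 2L - 1L)
    }
  }
  scen
}

# Sub-branch position geometry: given branch ids (integer index into
# `lens`), 1-based indices within each branch, the per-branch parent/child
# node names and the node distance matrix (in sub-branch units), return the
# full matrix of rearrangement distances between all positions.
position_distance_matrix <- function(branch, index, lens, par, chi, D) {
  off_p <- index - 1
  off_c <- lens[branch] - index
  n1 <- par[branch]
  n2 <- chi[branch]
  cand <- pmin(outer(off_p, off_p, "+") + D[n1, n1],
               outer(off_p, off_c, "+") + D[n1, n2],
               outer(off_c, off_p, "+") + D[n2, n1],
               outer(off_c, off_c, "+") + D[n2, n2]) + 1
  same <- outer(branch, branch, "==")
  direct <- abs(outer(index, index, "-"))
  cand[same] <- direct[same]
  cand
}

#' Actual multispecies breakpoint-reuse curve R(l)
#'
#' For every unordered pair of 2-breaks in a scenario-annotated tree,
#' accumulates the number of vertices both use (`br(rho1, rho2)`) and the
#' pair count, binned by the rearrangement distance l between the 2-breaks
#' (number of 2-breaks strictly between them on the tree path, plus one).
#' R(l) is the ratio; bins with no pairs are omitted.
#'
#' @param st A `scenario_tree` with scenarios on all branches.
#' @return A `reuse_curve` data frame with columns `l`, `total_reuse`,
#'   `pair_count`, `R`.
#' @export
actual_R_curve <- function(st) {
  nm <- names(st$scenarios)
  lens <- vapply(st$scenarios, nrow, 1L)
  keep <- lens > 0L
  nm <- nm[keep]
  lens <- lens[keep]
  if (length(nm) == 0L || sum(lens) < 2L)
    return(empty_reuse_curve())
  vm <- do.call(rbind, lapply(st$scenarios[nm], function(s) s[, 1:4, drop = FALSE]))
  branch <- rep(seq_along(nm), lens)
  index <- unlist(lapply(lens, seq_len), use.names = FALSE)
  D <- node_distance_matrix(st$tree)
  Dmat <- position_distance_matrix(branch, index, lens,
                                   st$from[nm], st$to[nm], D)
  as_reuse_curve(reuse_curve_from_usage(vm, Dmat, length(st$genomes[[1L]]$adj)))
}

reuse_curve_from_usage <- function(vm, Dmat, nv) {
  U <- Matrix::sparseMatrix(i = rep(seq_len(nrow(vm)), 4L),
                            j = as.vector(vm), x = 1, dims = c(nrow(vm), nv))
  S <- as.matrix(Matrix::tcrossprod(U))
  up <- upper.tri(S)
  grp <- factor(Dmat[up])
  tot <- tapply(S[up], grp, sum)
  cnt <- tabulate(grp)
  data.frame(l = as.numeric(levels(grp)), total_reuse = as.numeric(tot),
             pair_count = cnt, R = as.numeric(tot) / cnt)
}

empty_reuse_curve <- function() {
  structure(data.frame(l = numeric(0), total_reuse = numeric(0),
                       pair_count = integer(0), R = numeric(0)),
            class = c("reuse_curve", "data.frame"))
}

as_reuse_curve <- function(df) {
  class(df) <- c("reuse_curve", "data.frame")
  df
}

#' Empirical multispecies breakpoint-reuse curve
#'
#' When only the genomes at the tree nodes are known (no true scenarios),
#' the curve is estimated by sampling: each sampling draws an independent
#' shortest 2-break scenario on every branch with
#' [sample_shortest_scenario()], partitions each branch `e` into
#' `d(P, Q)` sub-branches carrying one 2-break each, and accumulates
#' shared-vertex counts and pair counts over all sub-branch pairs by their
#' rearrangement distance.  Totals are accumulated across samplings before
#' the final division, so every distance bin is averaged consistently.
#' Pairs on the same branch are included; they dominate the small-l bins.
#'
#' @param tr A `rearr_tree`.
#' @param genomes Named list of `genome`s at *all* tree nodes (leaves and
#'   ancestors).
#' @param num_samplings Number of independent scenario samplings averaged.
#' @param seed Optional integer seed.
#' @return A `reuse_curve` data frame (`l`, `total_reuse` averaged per
#'   sampling, `pair_count` per sampling, `R`).
#' @export
empirical_R_curve <- function(tr, genomes, num_samplings = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- tr$edges$name
  par <- structure(tr$edges$parent, names = nm)
  chi <- structure(tr$edges$child, names = nm)
  missing <- setdiff(tr$nodes, names(genomes))
  if (length(missing))
    stop("genomes required at every tree node; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bgs <- lapply(nm, function(e) breakpoint_graph(genomes[[par[e]]],
                                                 genomes[[chi[e]]]))
  names(bgs) <- nm
  lens <- vapply(bgs, function(b) b$b - b$c, 1L)   # sub-branch counts
  keep <- lens > 0L
  nmk <- nm[keep]
  if (length(nmk) == 0L || sum(lens[keep]) < 2L) return(empty_reuse_curve())
  # node distances measured in sub-branches (sampled scenario lengths)
  D <- node_distance_matrix(tr, lengths = ifelse(keep, lens, 0L))
  branch <- rep(seq_along(nmk), lens[keep])
  index <- unlist(lapply(lens[keep], seq_len), use.names = FALSE)
  Dmat <- position_distance_matrix(branch, index, lens[keep],
                                   par[nmk], chi[nmk], D)
  nv <- length(genomes[[1L]]$adj)
  up <- upper.tri(Dmat)
  grp <- factor(Dmat[up])
  cnt <- tabulate(grp)
  acc <- numeric(nlevels(grp))
  ntc <- lapply(bgs[nmk], function(b) b$cycles[!b$trivial])
  for (s in seq_len(num_samplings)) {
    vm <- do.call(rbind, lapply(ntc, function(cy)
      sample_scenario_from_cycles(cy)[, 1:4, drop = FALSE]))
    U <- Matrix::sparseMatrix(i = rep(seq_len(nrow(vm)), 4L),
                              j = as.vector(vm), x = 1,
                              dims = c(nrow(vm), nv))
    S <- as.matrix(Matrix::tcrossprod(U))
    acc <- acc + as.numeric(tapply(S[up], grp, sum))
  }
  as_reuse_curve(data.frame(l = as.numeric(levels(grp)),
                            total_reuse = acc / num_samplings,
                            pair_count = cnt,
                            R = acc / num_samplings / cnt))
}

#' Export a reuse curve as TSV
#' @param curve A `reuse_curve`.
#' @param path Output path.
#' @export
write_reuse_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reuse curve written by [write_reuse_curve()]
#' @param path TSV path with columns `l`, `total_reuse`, `pair_count`, `R`.
#' @return A `reuse_curve` data frame.
#' @export
read_reuse_curve <- function(path) {
  as_reuse_curve(utils::read.delim(path))
}
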