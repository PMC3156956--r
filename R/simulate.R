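#' Fragility state of a genome
#'
#' Under the fragile breakage models, only a subset of a genome's
#' adjacencies (inter-block regions) can be broken.  A fragility state
#' partitions the current adjacencies into n fragile and m - n solid sites.
#' Each adjacency is tracked by a handle: one of its extremities, from
#' which the adjacency is `(handle, adj[handle])`.  The two adjacencies
#' created by a 2-break inherit fragile status before turnover applies, so
#' |fragile| stays n after every step.
#'
#' @param g A `genome`.
#' @param n Number of fragile adjacencies (`n <= m`, the block count).
#' @param seed Optional seed used to draw the initial fragile set.
#' @return An object of class `"fragility_state"`: integer handle vectors
#'   `fragile` (length n) and `solid` (length m - n).
#' @export
fragility_state <- function(g, n, seed = NULL) {
  m <- n_blocks(g)
  n <- as.integer(n)
  if (n < 1L || n > m) stop("'n' must be between 1 and the block count",
                            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  reps <- which(seq_along(g$adj) < g$adj)   # one handle per adjacency
  frag <- sample(reps, n)
  structure(list(fragile = frag, solid = setdiff(reps, frag)),
            class = "fragility_state")
}

#' Fragile extremities of a fragility state
#' @param g A `genome`.
#' @param state A `fragility_state` for `g`.
#' @return Integer ids of the 2n extremities on fragile adjacencies.
#' @export
fragile_vertices <- function(g, state) {
  sort(c(state$fragile, g$adj[state$fragile]))
}

#' One TFBM simulation step
#'
#' Draws two distinct fragile adjacencies uniformly, reconnects their four
#' extremities by one of the two possible 2-breaks (chosen uniformly), marks
#' the two new adjacencies fragile, and then applies turnover: `x` uniformly
#' chosen fragile adjacencies become solid and `x` uniformly chosen solid
#' adjacencies become fragile.  With `x = 0` this is an FBM step (and an RBM
#' step when additionally n = m).
#'
#' @param g A `genome`.
#' @param state A `fragility_state` for `g`.
#' @param x Non-negative integer turnover rate per 2-break; must satisfy
#'   `x <= min(|fragile|, |solid|)`.
#' @return A list with the applied `two_break`, the new `genome` and the new
#'   `fragility_state`.
#' @export
tfbm_step <- function(g, state, x = 0L) {
  x <- as.integer(x)
  if (length(state$fragile) < 2L)
    stop("need at least two fragile adjacencies", call. = FALSE)
  if (x > min(length(state$fragile), length(state$solid)))
    stop("turnover rate x exceeds min(|fragile|, |solid|)", call. = FALSE)
  res <- simulate_branch_steps(g$adj, state$fragile, state$solid, 1L, x)
  s <- res$scenario[1L, ]
  tb <- structure(list(broken1 = s[1:2], broken2 = s[3:4],
                       joined1 = s[5:6], joined2 = s[7:8]),
                  class = "two_break")
  list(two_break = tb,
       genome = new_genome(res$adj, g$labels),
       state = structure(list(fragile = res$frag, solid = res$solid),
                         class = "fragility_state"))
}

# Fast inner loop shared by tfbm_step and simulate_tree.  `frag` and
# `solid` hold one extremity handle per adjacency; solid adjacencies are
# never broken, so their handles stay valid across steps.
simulate_branch_steps <- function(adj, frag, solid, L, x, record = TRUE) {
  n <- length(frag)
  scen <- if (record && L > 0L) matrix(0L, L, 8L) else NULL
  ns <- length(solid)
  for (s in seq_len(L)) {
    idx <- sample.int(n, 2L)
    u <- frag[idx[1L]]; v <- adj[u]
    w <- frag[idx[2L]]; y <- adj[w]
    if (sample.int(2L, 1L) == 1L) {      # join (u,w), (v,y)
      adj[u] <- w; adj[w] <- u; adj[v] <- y; adj[y] <- v
      row <- c(u, v, w, y, u, w, v, y)
      frag[idx[1L]] <- u; frag[idx[2L]] <- v
    } else {                             # join (u,y), (v,w)
      adj[u] <- y; adj[y] <- u; adj[v] <- w; adj[w] <- v
      row <- c(u, v, w, y, u, y, v, w)
      frag[idx[1L]] <- u; frag[idx[2L]] <- v
    }
    if (x > 0L) {
      die <- sample.int(n, x)
      born <- sample.int(ns, x)
      tmp <- frag[die]
      frag[die] <- solid[born]
      solid[born] <- tmp
    }
    if (record) scen[s, ] <- row
  }
  list(adj = adj, frag = frag, solid = solid, scenario = scen)
}

#' Simulation configuration for tree-structured TFBM evolution
#'
#' @param m Total number of breakable sites; equals the synteny block count
#'   of the simulated genomes.
#' @param n Number of simultaneously fragile sites (`n <= m`).
#' @param x Turnover rate per 2-break (`x <= min(n, m - n)` unless `x = 0`).
#' @param chromosomes Number of circular chromosomes in the start genome.
#' @param tree A `rearr_tree`; its integer branch lengths are the 2-break
#'   counts simulated per branch.
#' @param start Node at which the random start genome is placed; defaults to
#'   the first leaf.  Evolution is propagated from this node across the
#'   whole tree.
#' @param seed Integer RNG seed.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(m = 2000L, n = 900L, x = 0L,
                              chromosomes = 20L, tree = five_species_tree(),
                              start = NULL, seed = NULL) {
  m <- as.integer(m); n <- as.integer(n); x <- as.integer(x)
  if (n > m) stop("config error: n must not exceed m", call. = FALSE)
  if (x > 0L && x > min(n, m - n))
    stop("config error: x must not exceed min(n, m - n)", call. = FALSE)
  if (chromosomes > m) stop("config error: chromosomes > m", call. = FALSE)
  if (is.null(start)) {
    leaves <- setdiff(tree$nodes, tree$edges$parent)
    start <- leaves[1L]
  }
  if (!start %in% tree$nodes) stop("config error: unknown start node",
                                   call. = FALSE)
  structure(list(m = m, n = n, x = x, chromosomes = as.integer(chromosomes),
                 tree = tree, start = start, seed = seed),
            class = "sim_config")
}

#' Simulate TFBM evolution along a phylogenetic tree
#'
#' Places a random genome with the configured number of circular
#' chromosomes at the start node, then traverses the tree from that node,
#' simulating exactly `length(e)` 2-breaks on every branch `e` with
#' [tfbm_step()] dynamics.  The genome and fragility state at each internal
#' node are snapshotted and inherited by all branches leaving it, so
#' fragility evolves continuously along every root-to-leaf path.
#'
#' Branch scenarios are recorded in traversal orientation (from the node
#' nearer the start).  Because 2-breaks are invertible, the choice of start
#' node only fixes this orientation.
#'
#' @param config A `sim_config`.
#' @return An object of class `"scenario_tree"`: the tree, the start node,
#'   per-node `genome`s, per-branch scenario matrices (columns `u, v, x, y`
#'   broken and `j1a, j1b, j2a, j2b` joined extremities, one row per
#'   2-break), per-branch `from`/`to` orientation, and the config.
#' @examples
#' st <- simulate_tree(simulation_config(m = 200, n = 90, x = 1,
#'                                       chromosomes = 4, seed = 1))
#' st
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tr <- config$tree
  g0 <- random_genome(config$m, config$chromosomes)
  st0 <- fragility_state(g0, config$n)
  genomes <- list()
  scenarios <- list()
  from <- character(nrow(tr$edges)); names(from) <- tr$edges$name
  to <- from
  genomes[[config$start]] <- g0
  states <- list()
  states[[config$start]] <- st0
  # undirected adjacency over edges, traversed outward from the start node
  visit <- function(node) {
    hits <- which((tr$edges$parent == node & !(tr$edges$child %in% names(genomes))) |
                  (tr$edges$child == node & !(tr$edges$parent %in% names(genomes))))
    for (r in hits) {
      nxt <- if (tr$edges$parent[r] == node) tr$edges$child[r] else tr$edges$parent[r]
      if (nxt %in% names(genomes)) next
      stt <- states[[node]]
      res <- simulate_branch_steps(genomes[[node]]$adj, stt$fragile,
                                   stt$solid, tr$edges$length[r], config$x)
      nm <- tr$edges$name[r]
      scen <- res$scenario
      if (is.null(scen)) scen <- matrix(0L, 0L, 8L)
      colnames(scen) <- c("u", "v", "x", "y", "j1a", "j1b", "j2a", "j2b")
      scenarios[[nm]] <<- scen
      from[nm] <<- node
      to[nm] <<- nxt
      genomes[[nxt]] <<- new_genome(res$adj, genomes[[node]]$labels)
      states[[nxt]] <<- structure(list(fragile = res$frag, solid = res$solid),
                                  class = "fragility_state")
      visit(nxt)
    }
  }
  visit(config$start)
  structure(list(tree = tr, start = config$start, genomes = genomes,
                 scenarios = scenarios, from = from, to = to,
                 config = config),
            class = "scenario_tree")
}

#' @export
print.scenario_tree <- function(x, ...) {
  cat("Scenario tree:", length(x$genomes), "genomes on",
      length(x$scenarios), "branches;",
      sum(vapply(x$scenarios, nrow, 1L)), "2-breaks total",
      "(m =", x$config$m, ", n =", x$config$n, ", x =", x$config$x, ")\n")
  invisible(x)
}

#' Extract a branch scenario as a list of 2-breaks
#' @param st A `scenario_tree`.
#' @param branch Branch name.
#' @return List of `two_break` objects in traversal order.
#' @export
branch_scenario <- function(st, branch) {
  scen <- st$scenarios[[branch]]
  if (is.null(scen)) stop("unknown branch: ", branch, call. = FALSE)
  lapply(seq_len(nrow(scen)), function(i)
    structure(list(broken1 = scen[i, 1:2], broken2 = scen[i, 3:4],
                   joined1 = scen[i, 5:6], joined2 = scen[i, 7:8]),
              class = "two_break"))
}

#' Serialize a scenario tree to plain-text files
#'
#' Writes one GRIMM file with all node genomes and one TSV per branch with
#' the ordered 2-break log (columns: step, broken and joined adjacencies as
#' `"<block>t"`/`"<block>h"` extremity labels).
#'
#' @param st A `scenario_tree`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_tree <- function(st, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grimm(st$genomes, file.path(dir, "genomes.grimm"))
  write_rearr_tree(st$tree, file.path(dir, "tree.nwk"))
  g <- st$genomes[[1L]]
  for (nm in names(st$scenarios)) {
    scen <- st$scenarios[[nm]]
    df <- data.frame(step = seq_len(nrow(scen)))
    for (col in colnames(scen))
      df[[col]] <- extremity_label(g, scen[, col])
    utils::write.table(df, file.path(dir, paste0("scenario_", sub("\\+$", "", nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
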