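#' Phylogenetic trees with rearrangement branch lengths
#'
#' A rearrangement tree is a rooted tree whose branch lengths are
#' non-negative integers counting 2-breaks.  Every branch is stored with an
#' explicit parent-to-child direction and named `"<child>+"`, so the five
#' species tree has branches `M+`, `R+`, `D+`, `Q+`, `H+`, `MR+`, `QH+`.
#'
#' @param edges A data frame with columns `parent`, `child` (node names)
#'   and `length` (non-negative integer 2-break counts).
#' @return An object of class `"rearr_tree"`: the edge table (with a `name`
#'   column added), the node vector and the node-to-node distance matrix in
#'   2-breaks.
#' @seealso [five_species_tree()], [read_rearr_tree()],
#'   [branch_midpoint_distance()], [branch_pair_class()]
#' @export
rearr_tree <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  if (is.null(edges$length)) edges$length <- 1L
  if (any(edges$length < 0) || any(edges$length != trunc(edges$length)))
    stop("branch lengths must be non-negative integers (2-break counts)",
         call. = FALSE)
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  edges$length <- as.integer(edges$length)
  edges$name <- paste0(edges$child, "+")
  nodes <- unique(c(edges$parent, edges$child))
  if (anyDuplicated(edges$child) || length(nodes) != nrow(edges) + 1L)
    stop("edges must describe a tree: each child once, nodes = edges + 1",
         call. = FALSE)
  tr <- structure(list(edges = edges, nodes = nodes), class = "rearr_tree")
  tr$node_dist <- node_distance_matrix(tr)
  tr
}

#' @export
print.rearr_tree <- function(x, ...) {
  cat("Rearrangement tree:", length(x$nodes), "nodes,", nrow(x$edges),
      "branches (total length", sum(x$edges$length), ")\n")
  print(x$edges[, c("name", "parent", "child", "length")], row.names = FALSE)
  invisible(x)
}

# All-pairs node distances (sum of branch lengths along the unique path),
# and the edge path structure, by BFS from every node.
node_distance_matrix <- function(tr, lengths = NULL) {
  nodes <- tr$nodes
  k <- length(nodes)
  len <- if (is.null(lengths)) tr$edges$length else lengths
  nb <- lapply(seq_len(k), function(i) {
    hits <- which(tr$edges$parent == nodes[i] | tr$edges$child == nodes[i])
    other <- ifelse(tr$edges$parent[hits] == nodes[i],
                    tr$edges$child[hits], tr$edges$parent[hits])
    list(idx = match(other, nodes), w = len[hits])
  })
  D <- matrix(0, k, k, dimnames = list(nodes, nodes))
  for (s in seq_len(k)) {
    dist <- rep(NA_real_, k)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nbs <- nb[[v]]
      for (t in seq_along(nbs$idx)) {
        u <- nbs$idx[t]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + nbs$w[t]
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

# Number of edges (branches) on the path between two nodes.
node_edge_count_matrix <- function(tr) {
  tr2 <- tr
  node_distance_matrix(tr2, lengths = rep(1L, nrow(tr$edges)))
}

branch_index <- function(tr, e) {
  i <- match(e, tr$edges$name)
  if (is.na(i)) i <- match(paste0(e, "+"), tr$edges$name)
  if (is.na(i)) stop("unknown branch: ", e, call. = FALSE)
  i
}

#' The five-species rearrangement tree
#'
#' The tree on leaf genomes M, R, D, Q, H with ancestors MR (of M, R),
#' MRD (of MR, D and the QH subtree) and QH (of Q, H), i.e. the topology
#' ((M,R)MR,D)MRD,(Q,H)QH with seven branches M+, R+, D+, Q+, H+, MR+,
#' QH+.  The tree is rooted at MRD for branch orientation.
#'
#' @param lengths Named branch lengths in 2-breaks; names are branch names
#'   with or without the trailing `+`.  Defaults to 100 on every branch,
#'   the standard simulation protocol.
#' @return A `rearr_tree`.
#' @examples
#' five_species_tree()
#' five_species_tree(c(M = 56, MR = 170, QH = 58, H = 28))
#' @export
five_species_tree <- function(lengths = NULL) {
  edges <- data.frame(
    parent = c("MR", "MR", "MRD", "MRD", "MRD", "QH", "QH"),
    child  = c("M", "R", "MR", "D", "QH", "Q", "H"),
    length = 100L)
  if (!is.null(lengths)) {
    nm <- sub("\\+$", "", names(lengths))
    i <- match(nm, edges$child)
    if (anyNA(i)) stop("unknown branch in 'lengths': ", nm[is.na(i)][1L],
                       call. = FALSE)
    edges$length[i] <- as.integer(lengths)
  }
  rearr_tree(edges)
}

#' Read a rearrangement tree from a Newick file
#'
#' Internal nodes must be labelled (Newick node labels) so branches can be
#' named `"<child>+"`; branch lengths are rounded to integers.  The tree is
#' rooted as in the file.
#'
#' @param path Path to a Newick file.
#' @return A `rearr_tree`.
#' @export
read_rearr_tree <- function(path) {
  phy <- ape::read.tree(path)
  as_rearr_tree(phy)
}

#' Convert an ape `phylo` tree to a rearrangement tree
#' @param phy An `ape::phylo` object with node labels and edge lengths.
#' @return A `rearr_tree`.
#' @export
as_rearr_tree <- function(phy) {
  labs <- c(phy$tip.label,
            if (!is.null(phy$node.label)) phy$node.label
            else paste0("N", seq_len(phy$Nnode)))
  if (any(!nzchar(labs))) stop("all nodes must be labelled", call. = FALSE)
  len <- if (is.null(phy$edge.length)) rep(1, nrow(phy$edge)) else phy$edge.length
  rearr_tree(data.frame(parent = labs[phy$edge[, 1L]],
                        child = labs[phy$edge[, 2L]],
                        length = round(len)))
}

#' Write a rearrangement tree as Newick
#' @param tr A `rearr_tree`.
#' @param path Output path.
#' @export
write_rearr_tree <- function(tr, path) {
  ape::write.tree(as_phylo(tr), file = path)
  invisible(path)
}

as_phylo <- function(tr) {
  ed <- tr$edges
  children <- split(seq_len(nrow(ed)), ed$parent)
  root <- setdiff(tr$nodes, ed$child)
  rec <- function(node) {
    rows <- children[[node]]
    if (is.null(rows)) return(node)
    sub <- vapply(rows, function(r)
      paste0(rec(ed$child[r]), ":", ed$length[r]), "")
    paste0("(", paste(sub, collapse = ","), ")", node)
  }
  ape::read.tree(text = paste0(rec(root), ";"))
}

#' Distance between branch midpoints
#'
#' The total length of the tree path that starts at branch `e1` and ends at
#' branch `e2` (including both branches) minus half the two branch lengths;
#' zero when `e1 == e2`.  May be a half-integer.
#'
#' @param tr A `rearr_tree`.
#' @param e1,e2 Branch names (with or without the trailing `+`).
#' @return Non-negative number of 2-breaks (possibly ending in .5).
#' @examples
#' tr <- five_species_tree(c(M = 56, MR = 170, QH = 58, H = 28))
#' branch_midpoint_distance(tr, "M+", "H+")  # 270
#' @export
branch_midpoint_distance <- function(tr, e1, e2) {
  i <- branch_index(tr, e1)
  j <- branch_index(tr, e2)
  if (i == j) return(0)
  ed <- tr$edges
  D <- tr$node_dist
  ends <- function(r) c(ed$parent[r], ed$child[r])
  # facing endpoints: the pair of endpoints with minimal node distance
  gap <- min(D[ends(i), ends(j)])
  gap + ed$length[i] / 2 + ed$length[j] / 2
}

#' Classify a branch pair by tree separation
#'
#' Pairs of branches are `"red"` when they share a node (adjacent),
#' `"green"` when separated by exactly one intermediate branch, `"yellow"`
#' when separated by exactly two, and `"other"` beyond that.
#'
#' @param tr A `rearr_tree`.
#' @param e1,e2 Distinct branch names.
#' @return One of `"red"`, `"green"`, `"yellow"`, `"other"`.
#' @examples
#' tr <- five_species_tree()
#' branch_pair_class(tr, "M+", "R+")  # red
#' branch_pair_class(tr, "M+", "D+")  # green
#' branch_pair_class(tr, "M+", "H+")  # yellow
#' @export
branch_pair_class <- function(tr, e1, e2) {
  i <- branch_index(tr, e1)
  j <- branch_index(tr, e2)
  if (i == j) stop("branch pair classes are defined for distinct branches",
                   call. = FALSE)
  E <- node_edge_count_matrix(tr)
  ed <- tr$edges
  sep <- min(E[c(ed$parent[i], ed$child[i]), c(ed$parent[j], ed$child[j])])
  switch(as.character(sep), "0" = "red", "1" = "green", "2" = "yellow", "other")
}

#' All branch-pair classes of a tree
#'
#' @param tr A `rearr_tree`.
#' @return A data frame with one row per unordered branch pair: `e1`, `e2`,
#'   `class`.
#' @export
branch_pair_classes <- function(tr) {
  nm <- tr$edges$name
  k <- length(nm)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  data.frame(e1 = nm[pairs[, 1L]], e2 = nm[pairs[, 2L]],
             class = mapply(function(a, b) branch_pair_class(tr, a, b),
                            nm[pairs[, 1L]], nm[pairs[, 2L]],
                            USE.NAMES = FALSE))
}

#' Distance between two 2-breaks in a scenario-annotated tree
#'
#' Each branch `e` of length L carries an ordered scenario of L 2-breaks,
#' indexed 1..L from the parent end; a position is a (branch, index) pair.
#' The distance between two distinct positions is the number of 2-breaks
#' strictly between them along the unique tree path, plus one, so adjacent
#' 2-breaks are at distance 1.  It is symmetric and a metric on the
#' sub-branch positions of a fixed tree.
#'
#' @param tr A `rearr_tree` whose branch lengths equal the scenario lengths.
#' @param p1,p2 Positions: lists `list(branch =, index =)` with
#'   `1 <= index <= length(branch)`.
#' @return Positive integer distance.
#' @examples
#' tr <- five_species_tree()
#' rearrangement_distance(tr, list(branch = "M+", index = 3),
#'                            list(branch = "M+", index = 7))  # 4
#' @export
rearrangement_distance <- function(tr, p1, p2) {
  ed <- tr$edges
  i <- branch_index(tr, p1$branch)
  j <- branch_index(tr, p2$branch)
  a <- as.integer(p1$index)
  b <- as.integer(p2$index)
  if (a < 1L || a > ed$length[i] || b < 1L || b > ed$length[j])
    stop("position index outside the branch scenario", call. = FALSE)
  if (i == j) {
    if (a == b) stop("distance is defined for distinct 2-breaks", call. = FALSE)
    return(abs(a - b))
  }
  D <- tr$node_dist
  # offsets: 2-breaks strictly between the position and each branch end
  off1 <- c(a - 1L, ed$length[i] - a)     # to parent, to child
  off2 <- c(b - 1L, ed$length[j] - b)
  ends1 <- c(ed$parent[i], ed$child[i])
  ends2 <- c(ed$parent[j], ed$child[j])
  best <- Inf
  for (s in 1:2) for (t in 1:2)
    best <- min(best, off1[s] + D[ends1[s], ends2[t]] + off2[t])
  as.integer(best + 1L)
}
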