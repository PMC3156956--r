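#' Signed gene-order genomes with circular chromosomes
#'
#' A genome over m synteny blocks is stored as a perfect matching on the
#' 2m block extremities: the tail and head of every block.  An unordered
#' pair of matched extremities is an *adjacency* (two blocks that are
#' consecutive on a chromosome).  Together with the implicit "obverse"
#' tail--head edge inside each block, the matching decomposes into disjoint
#' alternating cycles, one per circular chromosome, so any perfect matching
#' on the extremities is a valid circular genome.
#'
#' Internally block i has tail extremity 2i-1 and head extremity 2i, and a
#' genome is a list with the partner vector `adj` (`adj[v]` is the extremity
#' matched to `v`) and the character vector `labels` of block names.  Block
#' ids are assigned by sorting the labels (numerically when every label is
#' an integer string), so two genomes over the same block set always agree
#' on the encoding.
#'
#' @param chromosomes A list of chromosomes.  Each chromosome is either a
#'   character vector of signed block names (`"+a"`, `"-d"`; a bare name
#'   means `+`) or a non-zero signed integer vector (`c(1, -3)` reads as
#'   `+1 -3`).  All chromosomes are circular.
#' @return An object of class `"genome"`.
#' @examples
#' P <- make_genome(list(c("+a", "+b"), c("+c", "+e", "-d")))
#' genome_chromosomes(P)
#' @seealso [read_grimm()], [random_genome()], [breakpoint_graph()]
#' @export
make_genome <- function(chromosomes) {
  if (!is.list(chromosomes) || length(chromosomes) == 0L)
    stop("'chromosomes' must be a non-empty list of block vectors", call. = FALSE)
  parsed <- lapply(chromosomes, parse_signed_blocks)
  labs <- unlist(lapply(parsed, `[[`, "label"), use.names = FALSE)
  if (length(labs) == 0L || anyNA(labs) || any(!nzchar(labs)))
    stop("invalid genome: empty chromosome or blank block label", call. = FALSE)
  if (anyDuplicated(labs))
    stop("invalid genome: duplicated block '",
         labs[anyDuplicated(labs)], "'", call. = FALSE)
  labels <- order_block_labels(labs)
  id <- match(labs, labels)
  m <- length(labels)
  adj <- integer(2L * m)
  pos <- 0L
  for (ch in parsed) {
    k <- length(ch$label)
    ids <- id[pos + seq_len(k)]
    pos <- pos + k
    sgn <- ch$sign
    enter <- ifelse(sgn > 0L, 2L * ids - 1L, 2L * ids)  # tail if +, head if -
    leave <- ifelse(sgn > 0L, 2L * ids, 2L * ids - 1L)
    nxt <- enter[c(seq_len(k)[-1L], 1L)]
    adj[leave] <- nxt
    adj[nxt] <- leave
  }
  new_genome(adj, labels)
}

new_genome <- function(adj, labels) {
  structure(list(adj = as.integer(adj), labels = as.character(labels)),
            class = "genome")
}

parse_signed_blocks <- function(ch) {
  if (is.numeric(ch)) {
    if (any(ch == 0) || any(ch != trunc(ch)))
      stop("numeric blocks must be non-zero integers", call. = FALSE)
    return(list(label = as.character(abs(ch)), sign = ifelse(ch > 0, 1L, -1L)))
  }
  ch <- as.character(ch)
  sgn <- ifelse(startsWith(ch, "-"), -1L, 1L)
  lab <- sub("^[+-]", "", ch)
  list(label = lab, sign = sgn)
}

order_block_labels <- function(labs) {
  u <- unique(labs)
  if (all(grepl("^[0-9]+$", u))) u[order(as.integer(u))]
  else u[order(u, method = "radix")]
}

#' @export
print.genome <- function(x, ...) {
  chs <- genome_chromosomes(x)
  cat("Circular genome:", n_blocks(x), "blocks,", length(chs), "chromosome(s)\n")
  for (ch in chs) cat("  (", paste(ch, collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' Number of synteny blocks of a genome
#' @param g A `genome`.
#' @return Integer block count.
#' @export
n_blocks <- function(g) length(g$labels)

#' Decompose a genome into signed circular chromosomes
#'
#' Each chromosome is reported in canonical orientation: traversal starts at
#' its smallest block id, read in the direction that gives that block a `+`
#' sign.
#'
#' @param g A `genome`.
#' @return A list of character vectors of signed block names.
#' @export
genome_chromosomes <- function(g) {
  m <- n_blocks(g)
  seen <- logical(m)
  out <- list()
  for (b in seq_len(m)) {
    if (seen[b]) next
    blocks <- character(0)
    cur <- b
    sgn <- 1L
    repeat {
      seen[cur] <- TRUE
      blocks <- c(blocks, paste0(if (sgn > 0L) "+" else "-", g$labels[cur]))
      leave <- if (sgn > 0L) 2L * cur else 2L * cur - 1L
      enter <- g$adj[leave]
      cur <- (enter + 1L) %/% 2L
      sgn <- if (enter %% 2L == 1L) 1L else -1L   # entered at tail => +
      if (cur == b) break
    }
    out[[length(out) + 1L]] <- blocks
  }
  out
}

#' Adjacencies of a genome
#'
#' @param g A `genome`.
#' @param labels If `TRUE` return extremity labels (`"ah"`, `"bt"`), else
#'   internal integer extremity ids.
#' @return A two-column matrix, one row per adjacency, columns sorted so the
#'   smaller extremity comes first.
#' @export
adjacencies <- function(g, labels = FALSE) {
  v <- which(seq_along(g$adj) < g$adj)
  mat <- cbind(v, g$adj[v])
  colnames(mat) <- c("e1", "e2")
  if (labels) {
    mat <- matrix(extremity_label(g, mat), ncol = 2L,
                  dimnames = list(NULL, c("e1", "e2")))
  }
  mat
}

#' Extremity labels
#'
#' Converts internal extremity ids to `"<block>t"` / `"<block>h"` labels and
#' back.
#'
#' @param g A `genome` (used for its block labels).
#' @param v Integer extremity ids (for `extremity_label`) or character labels
#'   (for `extremity_id`).
#' @return Character labels, or integer ids.
#' @export
extremity_label <- function(g, v) {
  paste0(g$labels[(v + 1L) %/% 2L], ifelse(v %% 2L == 1L, "t", "h"))
}

#' @rdname extremity_label
#' @export
extremity_id <- function(g, v) {
  lab <- sub("[th]$", "", v)
  end <- substring(v, nchar(v))
  id <- match(lab, g$labels)
  if (anyNA(id)) stop("unknown block label in extremity: ", v[is.na(id)][1L],
                      call. = FALSE)
  ifelse(end == "t", 2L * id - 1L, 2L * id)
}

#' Test two genomes for equality
#'
#' Genomes are equal when they are over the same block set and have the same
#' adjacency matching.
#'
#' @param g1,g2 `genome` objects.
#' @return Logical.
#' @export
genomes_equal <- function(g1, g2) {
  identical(g1$labels, g2$labels) && identical(g1$adj, g2$adj)
}

check_same_blocks <- function(P, Q) {
  if (!identical(P$labels, Q$labels))
    stop("incompatible genomes: different synteny block sets", call. = FALSE)
  invisible(TRUE)
}

#' Generate a random circular genome
#'
#' Draws a random signed arrangement of `m` blocks into the requested number
#' of non-empty circular chromosomes: a uniform permutation of the blocks
#' with independent uniform signs, cut at `chromosomes - 1` uniformly chosen
#' internal boundaries.
#'
#' @param m Number of synteny blocks; block labels are `"1" ... "m"`.
#' @param chromosomes Number of circular chromosomes (`<= m`).
#' @param seed Optional integer seed for reproducibility; `NULL` uses the
#'   current RNG state.
#' @return A `genome` with `m` blocks and `chromosomes` chromosomes.
#' @examples
#' g <- random_genome(10, chromosomes = 2, seed = 1)
#' length(genome_chromosomes(g))
#' @export
random_genome <- function(m, chromosomes = 1L, seed = NULL) {
  m <- as.integer(m)
  chromosomes <- as.integer(chromosomes)
  if (chromosomes > m || chromosomes < 1L)
    stop("'chromosomes' must be between 1 and m", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(m)
  sgn <- sample(c(1L, -1L), m, replace = TRUE)
  cuts <- if (chromosomes > 1L) sort(sample.int(m - 1L, chromosomes - 1L)) else integer(0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, m)
  chs <- lapply(seq_len(chromosomes), function(i) {
    idx <- starts[i]:ends[i]
    sgn[idx] * perm[idx]
  })
  make_genome(chs)
}
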