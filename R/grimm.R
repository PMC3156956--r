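#' Read and write genomes in GRIMM format
#'
#' GRIMM-style gene-order text: each genome starts with a header line
#' `>name`, followed by one line per chromosome listing whitespace-separated
#' signed block names terminated by `@` (circular chromosome).  Only
#' circular chromosomes are supported; a `$` terminator (linear chromosome)
#' is rejected.
#'
#' @param path Path to a GRIMM file (for `read_grimm`), or output path (for
#'   `write_grimm`).
#' @return `read_grimm` returns a named list of `genome` objects.
#' @examples
#' f <- tempfile()
#' writeLines(c(">P", "+a +b @", "+c +e -d @"), f)
#' read_grimm(f)
#' @export
read_grimm <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L || !startsWith(lines[1L], ">"))
    stop("GRIMM file must start with a '>name' header", call. = FALSE)
  genomes <- list()
  name <- NULL
  chrom <- list()
  flush <- function() {
    if (!is.null(name)) {
      if (length(chrom) == 0L)
        stop("genome '", name, "' has no chromosomes", call. = FALSE)
      genomes[[name]] <<- make_genome(chrom)
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      name <- trimws(substring(ln, 2L))
      chrom <- list()
    } else {
      toks <- strsplit(ln, "[ \t]+")[[1L]]
      term <- toks[length(toks)]
      if (term == "$")
        stop("linear chromosomes ('$' terminator) are not supported; ",
             "only circular chromosomes ('@') are handled", call. = FALSE)
      if (term != "@")
        stop("chromosome line must end with '@': ", ln, call. = FALSE)
      chrom[[length(chrom) + 1L]] <- toks[-length(toks)]
    }
  }
  flush()
  genomes
}

#' @rdname read_grimm
#' @param genomes A named list of `genome` objects, or a single `genome`.
#' @export
write_grimm <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genome = genomes)
  out <- character(0)
  for (name in names(genomes)) {
    out <- c(out, paste0(">", name))
    for (ch in genome_chromosomes(genomes[[name]]))
      out <- c(out, paste(c(ch, "@"), collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}
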