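#' Run a replicated breakage-model experiment
#'
#' Drives the standard simulation protocols: evolve a random 20-chromosome
#' genome along a phylogenetic tree under RBM, FBM, or TFBM for a number of
#' seeded replicates, and aggregate the breakpoint-reuse table (mean actual
#' and bound cells over replicates, class means over red/green/yellow
#' branch pairs, scaled reuse against the FBM expectation), optionally
#' together with sampled multispecies reuse curves and a TFBM parameter
#' fit.  Replicate r uses seed `seed + r`, so the whole bundle is
#' reproducible from `(configuration, seed)`.
#'
#' @param mode `"fbm"` (x = 0), `"rbm"` (x = 0 and n = m) or `"tfbm"`.
#' @param m Total breakable sites (block count of the simulated genomes).
#' @param n Fragile-site count; forced to `m` for `"rbm"`.
#' @param x Turnover rate; must be 0 for `"fbm"`/`"rbm"`.
#' @param tree A `rearr_tree` (default: five-species topology, all branch
#'   lengths 100).
#' @param chromosomes Start-genome chromosome count.
#' @param replicates Number of simulation replicates.
#' @param seed Base seed.
#' @param curves If `TRUE`, also sample an empirical reuse curve per
#'   replicate and return the pooled curve plus its TFBM fit.
#' @param num_samplings Scenario samplings per replicate for the curve.
#' @param out_dir Optional directory: writes `reuse_table.tsv/.json`,
#'   `curve.tsv`, `fit.json`, and a `manifest.json` describing the run.
#' @return A list of class `"tfbm_experiment"`: `mean_actual`,
#'   `mean_bound` (branch-pair matrices averaged over replicates),
#'   `class_means` and per-replicate `class_values`, `mean_inter` (mean
#'   actual inter-reuse over all branch pairs), `scaled` (mean actual
#'   divided by the FBM expectation per pair), and when `curves = TRUE`
#'   the pooled `curve` and `fit`.
#' @examples
#' ex <- run_experiment("fbm", m = 300, n = 150, replicates = 3, seed = 1,
#'                      chromosomes = 5)
#' ex$class_means
#' @export
run_experiment <- function(mode = c("fbm", "tfbm", "rbm"), m = 2000L,
                           n = 900L, x = 0L, tree = five_species_tree(),
                           chromosomes = 20L, replicates = 100L, seed = 1L,
                           curves = FALSE, num_samplings = 20L,
                           out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "rbm") n <- m
  if (mode %in% c("fbm", "rbm") && x != 0L)
    stop("config error: mode '", mode, "' requires x = 0", call. = FALSE)
  if (mode == "tfbm" && x <= 0L)
    stop("config error: mode 'tfbm' requires x > 0", call. = FALSE)
  nm <- tree$edges$name
  k <- length(nm)
  if (replicates < 1L) {
    out <- structure(list(mode = mode, replicates = 0L), class = "tfbm_experiment")
    return(out)
  }
  acc_actual <- matrix(0, k, k, dimnames = list(nm, nm))
  acc_bound <- matrix(0, k, k, dimnames = list(nm, nm))
  class_values <- matrix(NA_real_, replicates, 3,
                         dimnames = list(NULL, c("red", "green", "yellow")))
  rep_mean_inter <- numeric(replicates)
  curve_acc <- NULL
  classes <- NULL
  for (r in seq_len(replicates)) {
    cfg <- simulation_config(m = m, n = n, x = x, chromosomes = chromosomes,
                             tree = tree, seed = seed + r)
    st <- simulate_tree(cfg)
    rt <- reuse_table(st)
    if (is.null(classes)) classes <- rt$classes
    acc_actual <- acc_actual + rt$actual
    acc_bound <- acc_bound + rt$bound
    cm <- class_means(rt)
    class_values[r, names(cm)] <- cm
    up <- upper.tri(rt$actual)
    rep_mean_inter[r] <- mean(rt$actual[up])
    if (curves) {
      cv <- empirical_R_curve(tree, st$genomes, num_samplings = num_samplings)
      curve_acc <- pool_curves(curve_acc, cv)
    }
  }
  mean_actual <- acc_actual / replicates
  mean_bound <- acc_bound / replicates
  lens <- structure(tree$edges$length, names = nm)
  expect <- outer(lens, lens, function(a, b) expected_inter(n, a, b))
  diag(expect) <- expected_intra(n, pmax(lens, 1))
  out <- list(mode = mode, m = m, n = n, x = x, replicates = replicates,
              seed = seed, tree = tree,
              mean_actual = mean_actual, mean_bound = mean_bound,
              classes = classes,
              class_values = class_values,
              class_means = colMeans(class_values),
              class_se = apply(class_values, 2, stats::sd) / sqrt(replicates),
              mean_inter = mean(rep_mean_inter),
              se_inter = stats::sd(rep_mean_inter) / sqrt(replicates),
              scaled = mean_actual / expect,
              expected = expect)
  if (curves) {
    out$curve <- finalize_pooled_curve(curve_acc, replicates)
    out$fit <- tryCatch(fit_tfbm(out$curve), error = function(e) NULL)
  }
  class(out) <- "tfbm_experiment"
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

pool_curves <- function(acc, cv) {
  if (is.null(acc)) {
    cv$total_acc <- cv$total_reuse
    cv$count_acc <- cv$pair_count
    return(cv[, c("l", "total_acc", "count_acc")])
  }
  mg <- merge(acc, cv[, c("l", "total_reuse", "pair_count")],
              by = "l", all = TRUE)
  mg[is.na(mg)] <- 0
  mg$total_acc <- mg$total_acc + mg$total_reuse
  mg$count_acc <- mg$count_acc + mg$pair_count
  mg[, c("l", "total_acc", "count_acc")]
}

finalize_pooled_curve <- function(acc, replicates) {
  as_reuse_curve(data.frame(l = acc$l,
                            total_reuse = acc$total_acc / replicates,
                            pair_count = acc$count_acc / replicates,
                            R = acc$total_acc / acc$count_acc))
}

#' @export
print.tfbm_experiment <- function(x, ...) {
  if (x$replicates == 0L) {
    cat("Empty experiment (0 replicates)\n")
    return(invisible(x))
  }
  cat(sprintf("%s experiment: m = %d, n = %d, x = %d, %d replicates\n",
              toupper(x$mode), x$m, x$n, x$x, x$replicates))
  cat(sprintf("  mean inter-reuse over all branch pairs: %.2f (se %.2f)\n",
              x$mean_inter, x$se_inter))
  cm <- x$class_means
  cat(sprintf("  class means  red: %.2f  green: %.2f  yellow: %.2f\n",
              cm[["red"]], cm[["green"]], cm[["yellow"]]))
  invisible(x)
}

write_experiment <- function(ex, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(ex$mean_actual, file.path(out_dir, "reuse_table.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(mode = ex$mode, m = ex$m, n = ex$n, x = ex$x,
         replicates = ex$replicates, seed = ex$seed,
         mean_inter = ex$mean_inter,
         class_means = as.list(ex$class_means),
         scaled = ex$scaled, classes = ex$classes),
    file.path(out_dir, "reuse_table.json"),
    auto_unbox = TRUE, na = "null", digits = NA, pretty = TRUE)
  if (!is.null(ex$curve))
    write_reuse_curve(ex$curve, file.path(out_dir, "curve.tsv"))
  if (!is.null(ex$fit))
    write_tfbm_fit(ex$fit, file.path(out_dir, "fit.json"))
  manifest <- list(mode = ex$mode, m = ex$m, n = ex$n, x = ex$x,
                   chromosomes = 20L, replicates = ex$replicates,
                   seed = ex$seed,
                   package_version = as.character(utils::packageVersion("tfbm")),
                   files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Worked 5-block example of the breakpoint graph machinery
#'
#' Builds the two-chromosome genome P = (+a +b)(+c +e -d) and the
#' one-chromosome genome Q = (+a +b -e +c +d), reports the breakpoint-graph
#' invariants (b = 4 synteny blocks, c = 2 non-trivial cycles, distance
#' d = b - c = 2), the cycle listing with extremity labels, and one sampled
#' two-step shortest transformation of P into Q.
#'
#' @param seed Seed for the sampled transformation.
#' @return A list (JSON-serializable): genomes, `b`, `c`, `d`,
#'   `trivial_cycles`, `nontrivial_cycles`, and the sampled `scenario` with
#'   the intermediate genomes it visits.
#' @examples
#' demo_worked_example()$d  # 2
#' @export
demo_worked_example <- function(seed = 1L) {
  P <- make_genome(list(c("+a", "+b"), c("+c", "+e", "-d")))
  Q <- make_genome(list(c("+a", "+b", "-e", "+c", "+d")))
  bg <- breakpoint_graph(P, Q)
  lab <- function(v) extremity_label(P, v)
  scen <- sample_shortest_scenario(P, Q, seed = seed)
  steps <- list()
  g <- P
  for (i in seq_len(nrow(scen))) {
    tb <- structure(list(broken1 = scen[i, 1:2], broken2 = scen[i, 3:4],
                         joined1 = scen[i, 5:6], joined2 = scen[i, 7:8]),
                    class = "two_break")
    g <- apply_two_break(g, tb)
    steps[[i]] <- list(
      broken = list(lab(tb$broken1), lab(tb$broken2)),
      joined = list(lab(tb$joined1), lab(tb$joined2)),
      genome = vapply(genome_chromosomes(g),
                      function(ch) paste(ch, collapse = " "), ""))
  }
  list(P = vapply(genome_chromosomes(P), function(ch) paste(ch, collapse = " "), ""),
       Q = vapply(genome_chromosomes(Q), function(ch) paste(ch, collapse = " "), ""),
       b = bg$b, c = bg$c, d = bg$b - bg$c,
       trivial_cycles = lapply(bg$cycles[bg$trivial], lab),
       nontrivial_cycles = lapply(bg$cycles[!bg$trivial], lab),
       scenario = steps)
}
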