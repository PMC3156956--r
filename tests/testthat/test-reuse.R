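tb <- function(u, v, x, y, j1a, j1b, j2a, j2b) {
  structure(list(broken1 = c(u, v), broken2 = c(x, y),
                 joined1 = c(j1a, j1b), joined2 = c(j2a, j2b)),
            class = "two_break")
}

test_that("intra-reuse counts vertices used by at least two 2-breaks", {
  t1 <- tb(1, 2, 3, 4, 1, 3, 2, 4)
  expect_equal(intra_reuse(list(t1)), c(br = 0L, BR = 0L))
  # second 2-break shares exactly vertex 1
  t2 <- tb(1, 3, 5, 6, 1, 5, 3, 6)
  expect_equal(intra_reuse(list(t1, t2)), c(br = 2L, BR = 2L))
  # vertex used three times: BR exceeds br
  t3 <- tb(1, 5, 7, 8, 1, 7, 5, 8)
  ir <- intra_reuse(list(t1, t2, t3))
  expect_equal(ir[["br"]], 3L)   # vertices 1, 3, 5
  expect_equal(ir[["BR"]], 4L)   # vertex 1 used three times
  expect_gt(ir[["BR"]], ir[["br"]])
})

test_that("BR equals br when no vertex is used more than twice", {
  set.seed(91)
  for (i in 1:20) {
    g <- random_genome(60, chromosomes = 2)
    st <- fragility_state(g, 30)
    res <- tfbm:::simulate_branch_steps(g$adj, st$fragile, st$solid, 8L, 0L)
    cnt <- tabulate(res$scenario[, 1:4])
    ir <- intra_reuse(res$scenario)
    if (max(cnt) <= 2L) expect_equal(ir[["br"]], ir[["BR"]])
    expect_gte(ir[["BR"]], ir[["br"]])
  }
})

test_that("inter-reuse counts shared vertices once each", {
  t1 <- tb(1, 2, 3, 4, 1, 3, 2, 4)
  t2 <- tb(5, 6, 7, 8, 5, 7, 6, 8)
  expect_equal(inter_reuse(list(t1), list(t2)), 0L)
  expect_equal(inter_reuse(list(t1), list(t1)), 4L)
  expect_equal(inter_reuse(list(t1, t2), list(t1)), 4L)
  expect_equal(inter_reuse(list(t1), list(t2, t1)), 4L)
})

test_that("breakpoint-graph bounds match the worked example", {
  P <- worked_P(); Q <- worked_Q()
  expect_equal(bound_intra(P, Q), 0L)        # 4*2 - 2*4
  expect_equal(bound_intra(P, P), 0L)
  bg <- breakpoint_graph(P, Q)
  expect_equal(bound_inter(bg, bg), 8L)      # all non-trivial-cycle vertices
  expect_equal(bound_inter(bg, breakpoint_graph(P, P)), 0L)
})

test_that("expected FBM reuse follows the closed forms", {
  expect_equal(expected_inter(900, 0, 100), 0)
  expect_equal(expected_inter(500, 100, 100), 108.688872, tolerance = 1e-6)
  expect_equal(expected_inter(900, 100, 100), 71.470049, tolerance = 1e-6)
  expect_equal(expected_inter(1300, 100, 100), 52.867470, tolerance = 1e-6)
  # single 2-break cannot intra-reuse; formula clamps near zero
  n <- 900
  expect_lt(expected_intra(n, 1), 2 * n * (2 / n)^2)
  expect_gt(expected_intra(900, 100), 0)
  expect_lt(expected_intra(900, 100), expected_inter(900, 100, 100))
  expect_error(expected_intra(900, 0))
  expect_equal(scaled_reuse(71.47, 71.47), 1)
  expect_error(scaled_reuse(1, 0), "undefined scale")
})

test_that("simulated FBM inter-reuse matches its expectation", {
  set.seed(101)
  n <- 900L; t <- 100L; reps <- 40L
  tr <- rearr_tree(data.frame(parent = c("B", "B"), child = c("A", "C"),
                              length = t))
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- simulate_tree(simulation_config(m = 2000, n = n, x = 0,
                                          chromosomes = 20, tree = tr,
                                          seed = 200 + r))
    vals[r] <- inter_reuse(st$scenarios[["A+"]], st$scenarios[["C+"]])
  }
  se <- stats::sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - exact_fbm_inter(n, t, t)), 3 * se)
  # the exponential form is within a fraction of a percent of the exact one
  expect_equal(expected_inter(n, t, t), exact_fbm_inter(n, t, t),
               tolerance = 0.005)
})

test_that("simulated FBM intra-reuse matches its expectation", {
  set.seed(111)
  n <- 900L; t <- 100L; reps <- 40L
  tr <- rearr_tree(data.frame(parent = "A", child = "B", length = t))
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- simulate_tree(simulation_config(m = 2000, n = n, x = 0,
                                          chromosomes = 20, tree = tr,
                                          seed = 300 + r))
    vals[r] <- intra_reuse(st$scenarios[["B+"]])[["br"]]
  }
  se <- stats::sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - expected_intra(n, t)), 3 * se + 1)
})

test_that("reuse tables carry actual values, bounds, classes and flags", {
  st <- simulate_tree(simulation_config(m = 300, n = 140, x = 0,
                                        chromosomes = 5, seed = 121))
  rt <- reuse_table(st)
  expect_true(rt$has_scenarios)
  up <- upper.tri(rt$actual)
  expect_equal(rt$actual[up], t(rt$actual)[up])        # symmetric
  expect_equal(rt$bound[up], t(rt$bound)[up])
  expect_true(all(rt$actual[up] >= 0))
  expect_equal(unname(diag(rt$actual)), unname(rt$br))
  expect_equal(sum(rt$classes[up] == "red"), 9L)
  # bound equals actual inter-reuse wherever both scenarios are shortest
  for (i in 1:6) for (j in (i + 1):7) {
    if (rt$shortest[i] && rt$shortest[j])
      expect_equal(rt$actual[i, j], rt$bound[i, j])
  }
  # bounds-only table from genomes alone
  rt2 <- reuse_table(st$tree, st$genomes)
  expect_false(rt2$has_scenarios)
  expect_true(all(is.na(rt2$actual)))
  expect_equal(rt2$bound, rt$bound)
  # export round trip
  paths <- withr::local_tempfile(fileext = c(".tsv", ".json"))
  write_reuse_table(rt, tsv = paths[1], json = paths[2])
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[2])
  expect_equal(unlist(js$branches), rt$branches)
})
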