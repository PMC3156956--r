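test_that("fragility state partitions the adjacencies and is conserved", {
  g <- random_genome(100, chromosomes = 3, seed = 21)
  st <- fragility_state(g, 40, seed = 22)
  expect_length(st$fragile, 40L)
  expect_length(st$solid, 60L)
  expect_length(intersect(st$fragile, st$solid), 0L)
  res <- tfbm_step(g, st, x = 2)
  expect_length(res$state$fragile, 40L)
  expect_length(res$state$solid, 60L)
  # every handle still addresses a real adjacency of the new genome
  handles <- c(res$state$fragile, res$state$solid)
  expect_length(handles, 100L)
  expect_setequal(sort(c(handles, res$genome$adj[handles])),
                  seq_along(res$genome$adj))
  expect_error(tfbm_step(g, st, x = 45), "exceeds")
})

test_that("FBM steps (x = 0) never touch solid adjacencies", {
  set.seed(31)
  g <- random_genome(200, chromosomes = 4)
  st <- fragility_state(g, 80)
  solid0 <- sort(c(st$solid, g$adj[st$solid]))
  frag0 <- fragile_vertices(g, st)
  for (i in 1:50) {
    res <- tfbm_step(g, st, x = 0)
    expect_true(all(used_vertices(res$two_break) %in% frag0))
    g <- res$genome
    st <- res$state
  }
  # solid adjacencies are bitwise unchanged, fragile vertex set closed
  expect_equal(sort(c(st$solid, g$adj[st$solid])), solid0)
  expect_setequal(fragile_vertices(g, st), frag0)
})

test_that("a random 2-break uses a fixed fragile vertex with frequency 2/n", {
  set.seed(41)
  n <- 100L
  g <- random_genome(400, chromosomes = 4)
  st <- fragility_state(g, n)
  v <- st$fragile[1L]   # stays fragile forever under x = 0
  steps <- 10000L
  res <- tfbm:::simulate_branch_steps(g$adj, st$fragile, st$solid, steps, 0L)
  uses <- sum(res$scenario[, 1:4] == v)
  # Binomial(steps, 2/n): mean 200, sd ~ 14
  expect_lt(abs(uses - steps * 2 / n), 4 * sqrt(steps * 2 / n))
})

test_that("tree simulation produces consistent scenarios at every branch", {
  cfg <- simulation_config(m = 400, n = 180, x = 1, chromosomes = 5,
                           seed = 51)
  st <- simulate_tree(cfg)
  expect_equal(sum(vapply(st$scenarios, nrow, 1L)), 700L)
  for (e in st$tree$edges$name) {
    scen <- st$scenarios[[e]]
    expect_equal(nrow(scen), 100L)
    end <- apply_scenario(st$genomes[[st$from[[e]]]], scen)
    expect_true(genomes_equal(end, st$genomes[[st$to[[e]]]]))
    d <- two_break_distance(st$genomes[[st$from[[e]]]],
                            st$genomes[[st$to[[e]]]])
    expect_lte(d, 100L)
  }
})

test_that("simulation is reproducible and zero-length branches are inert", {
  cfg <- simulation_config(m = 200, n = 90, x = 2, chromosomes = 4, seed = 61)
  st1 <- simulate_tree(cfg)
  st2 <- simulate_tree(cfg)
  expect_identical(st1$scenarios, st2$scenarios)
  tr <- five_species_tree(c(M = 0))
  st3 <- simulate_tree(simulation_config(m = 200, n = 90, x = 0,
                                         chromosomes = 4, tree = tr, seed = 62))
  e <- "M+"
  expect_equal(nrow(st3$scenarios[[e]]), 0L)
  expect_true(genomes_equal(st3$genomes[[st3$from[[e]]]],
                            st3$genomes[[st3$to[[e]]]]))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(m = 100, n = 200), "n must not exceed m")
  expect_error(simulation_config(m = 100, n = 90, x = 20),
               "min\\(n, m - n\\)")
  expect_error(simulation_config(m = 10, n = 5, chromosomes = 11),
               "chromosomes")
  expect_error(simulation_config(start = "nope"), "start node")
})

test_that("fragile persistence tracks P(l) under turnover", {
  set.seed(71)
  m <- 2000L; n <- 900L; x <- 1L; L <- 400L
  reps <- 15L
  frac <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- random_genome(m, chromosomes = 20)
    st <- fragility_state(g, n)
    v0 <- fragile_vertices(g, st)
    res <- tfbm:::simulate_branch_steps(g$adj, st$fragile, st$solid, L, x)
    vL <- sort(c(res$frag, res$adj[res$frag]))
    frac[r] <- mean(v0 %in% vL)
  }
  target <- persistence_probability(L, n, x, m)
  se <- stats::sd(frac) / sqrt(reps)
  expect_lt(abs(mean(frac) - target), 3 * se + 0.005)
})

test_that("scenario trees serialize to plain text and round-trip genomes", {
  st <- simulate_tree(simulation_config(m = 50, n = 20, x = 1,
                                        chromosomes = 2, seed = 81))
  dir <- withr::local_tempdir()
  write_scenario_tree(st, dir)
  expect_true(file.exists(file.path(dir, "genomes.grimm")))
  expect_true(file.exists(file.path(dir, "tree.nwk")))
  expect_length(list.files(dir, pattern = "^scenario_.*tsv$"), 7L)
  back <- read_grimm(file.path(dir, "genomes.grimm"))
  for (nm in names(st$genomes))
    expect_true(genomes_equal(st$genomes[[nm]], back[[nm]]))
})
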