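test_that("sampled scenarios are shortest and transform P into Q", {
  P <- worked_P(); Q <- worked_Q()
  for (s in 1:10) {
    scen <- sample_shortest_scenario(P, Q, seed = s)
    expect_equal(nrow(scen), 2L)
    # each prefix decreases the distance by exactly one
    g <- P
    d <- two_break_distance(P, Q)
    for (i in seq_len(nrow(scen))) {
      g <- apply_two_break(g, scenario_row_as_two_break(scen, i))
      expect_equal(two_break_distance(g, Q), d - i)
    }
    expect_true(genomes_equal(g, Q))
  }
  expect_equal(nrow(sample_shortest_scenario(P, P, seed = 1)), 0L)
})

test_that("sampled scenarios on random genomes have length b - c", {
  set.seed(131)
  for (i in 1:20) {
    P <- random_genome(8, chromosomes = sample(1:2, 1))
    Q <- random_genome(8, chromosomes = sample(1:2, 1))
    bg <- breakpoint_graph(P, Q)
    scen <- sample_shortest_scenario(P, Q)
    expect_equal(nrow(scen), bg$b - bg$c)
    expect_true(genomes_equal(apply_scenario(P, scen), Q))
  }
})

test_that("first-step 2-breaks are uniform over the splitting choices", {
  # single 6-edge cycle: exactly 3 splitting 2-breaks
  P <- make_genome(list(c(1, 2, 3)))
  Q <- make_genome(list(c(1, -2, -3)))
  bg <- breakpoint_graph(P, Q)
  expect_equal(bg$c, 1L)
  expect_equal(length(bg$cycles[!bg$trivial][[1]]), 6L)
  expect_length(splitting_two_breaks(bg$cycles[!bg$trivial][[1]]), 3L)
  set.seed(141)
  draws <- 3000L
  first <- character(draws)
  for (s in seq_len(draws)) {
    scen <- sample_shortest_scenario(P, Q, bg = bg)
    first[s] <- paste(sort(scen[1, 1:4]), collapse = ",")
  }
  counts <- table(first)
  expect_length(counts, 3L)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("cycles are selected proportionally to |C|/2 - 1", {
  # two non-trivial cycles with weights 1 and 2
  P <- make_genome(list(c(1, 2), c(3, 4, 5)))
  Q <- make_genome(list(c(1, -2), c(3, -4, -5)))
  bg <- breakpoint_graph(P, Q)
  w <- lengths(bg$cycles[!bg$trivial]) / 2 - 1
  expect_setequal(w, c(1, 2))
  big <- bg$cycles[!bg$trivial][[which(w == 2)]]
  set.seed(151)
  draws <- 3000L
  hits <- 0L
  for (s in seq_len(draws)) {
    scen <- sample_shortest_scenario(P, Q, bg = bg)
    if (scen[1, 1] %in% big) hits <- hits + 1L
  }
  # P(big cycle first) = 2/3; binomial sd ~ 0.0086
  expect_lt(abs(hits / draws - 2 / 3), 4 * sqrt(2 / 9 / draws))
})

test_that("actual R curves handle degenerate scenario trees", {
  tr <- rearr_tree(data.frame(parent = "A", child = "B", length = 2))
  g <- random_genome(10, chromosomes = 1, seed = 161)
  fake_st <- function(scen) {
    structure(list(tree = tr, start = "A",
                   genomes = list(A = g, B = g),
                   scenarios = list("B+" = scen),
                   from = c("B+" = "A"), to = c("B+" = "B")),
              class = "scenario_tree")
  }
  one <- matrix(c(1L, 2L, 3L, 4L, 1L, 3L, 2L, 4L), 1)
  expect_equal(nrow(actual_R_curve(fake_st(one[0, , drop = FALSE]))), 0L)
  # two identical 2-breaks at distance 1 share all four vertices
  cv <- actual_R_curve(fake_st(rbind(one, one)))
  expect_equal(cv$l, 1)
  expect_equal(cv$R, 4)
  expect_equal(cv$pair_count, 1L)
})

test_that("RBM actual reuse is flat near 8/n", {
  set.seed(171)
  n <- 400L
  tr <- rearr_tree(data.frame(parent = "A", child = "B", length = 200))
  ratios <- numeric(3)
  for (r in 1:3) {
    st <- simulate_tree(simulation_config(m = n, n = n, x = 0,
                                          chromosomes = 5, tree = tr,
                                          seed = 180 + r))
    cv <- actual_R_curve(st)
    ratios[r] <- sum(cv$total_reuse) / sum(cv$pair_count) / (8 / n)
  }
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("empirical curves are reproducible and nearly horizontal on one branch", {
  tr <- rearr_tree(data.frame(parent = "A", child = "B", length = 60))
  st <- simulate_tree(simulation_config(m = 500, n = 200, x = 1,
                                        chromosomes = 5, tree = tr,
                                        seed = 191))
  cv1 <- empirical_R_curve(tr, st$genomes, num_samplings = 5, seed = 192)
  cv2 <- empirical_R_curve(tr, st$genomes, num_samplings = 5, seed = 192)
  expect_identical(cv1, cv2)
  expect_true(all(cv1$pair_count > 0))
  expect_true(all(cv1$R >= 0))
})

test_that("sampling variance of the curve mean is small", {
  tr1 <- rearr_tree(data.frame(parent = "A", child = "B", length = 400))
  st <- simulate_tree(simulation_config(m = 2000, n = 900, x = 1,
                                        chromosomes = 20, tree = tr1,
                                        seed = 201))
  means <- vapply(1:20, function(s) {
    cv <- empirical_R_curve(tr1, st$genomes, num_samplings = 1,
                            seed = 210 + s)
    sum(cv$total_reuse) / sum(cv$pair_count)
  }, 0)
  expect_lt(stats::sd(means), 0.1 * mean(means))
})

test_that("reuse curves round-trip through TSV", {
  df <- data.frame(l = 1:5, total_reuse = c(4, 3, 2, 1, 0),
                   pair_count = 5:1, R = c(4, 3, 2, 1, 0) / (5:1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reuse_curve(df, f)
  back <- read_reuse_curve(f)
  expect_equal(as.data.frame(back), df)
})
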