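test_that("midpoint distances match the worked path computation", {
  tr <- five_species_tree(c(M = 56, MR = 170, QH = 58, H = 28))
  expect_equal(branch_midpoint_distance(tr, "M+", "H+"), 270)
  expect_equal(branch_midpoint_distance(tr, "M+", "M+"), 0)
  # two adjacent branches of length 100: 200 - (100 + 100)/2
  tr2 <- rearr_tree(data.frame(parent = c("A", "B"), child = c("B", "C"),
                               length = c(100, 100)))
  expect_equal(branch_midpoint_distance(tr2, "B+", "C+"), 100)
  # half-integer case
  tr3 <- rearr_tree(data.frame(parent = c("A", "B"), child = c("B", "C"),
                               length = c(3, 4)))
  expect_equal(branch_midpoint_distance(tr3, "B+", "C+"), 3.5)
  expect_error(branch_midpoint_distance(tr, "Z+", "M+"), "unknown branch")
})

test_that("branch pairs classify red/green/yellow by separation", {
  tr <- five_species_tree()
  expect_equal(branch_pair_class(tr, "M+", "R+"), "red")
  expect_equal(branch_pair_class(tr, "M+", "D+"), "green")
  expect_equal(branch_pair_class(tr, "M+", "H+"), "yellow")
  cls <- branch_pair_classes(tr)
  expect_equal(nrow(cls), 21L)
  expect_equal(unname(table(cls$class)[c("red", "green", "yellow")]),
               c(9L, 8L, 4L), ignore_attr = TRUE)
})

test_that("rearrangement distance counts 2-breaks between positions plus one", {
  tr <- five_species_tree()
  pos <- function(b, i) list(branch = b, index = i)
  # same branch: |i - j|
  expect_equal(rearrangement_distance(tr, pos("M+", 3), pos("M+", 4)), 1L)
  expect_equal(rearrangement_distance(tr, pos("M+", 3), pos("M+", 10)), 7L)
  # the 2-breaks nearest the shared node of two sibling branches are adjacent
  expect_equal(rearrangement_distance(tr, pos("M+", 1), pos("R+", 1)), 1L)
  # ... and the far ends of two siblings span both branches
  expect_equal(rearrangement_distance(tr, pos("M+", 100), pos("R+", 100)), 199L)
  # crossing an intermediate branch adds its full length
  expect_equal(rearrangement_distance(tr, pos("M+", 1), pos("D+", 1)), 101L)
  # symmetry and error cases
  expect_equal(rearrangement_distance(tr, pos("D+", 1), pos("M+", 1)), 101L)
  expect_error(rearrangement_distance(tr, pos("M+", 3), pos("M+", 3)),
               "distinct")
  expect_error(rearrangement_distance(tr, pos("M+", 101), pos("M+", 1)),
               "outside")
})

test_that("rearrangement distance is a metric on a toy tree", {
  tr <- rearr_tree(data.frame(parent = c("A", "B", "B"),
                              child = c("B", "C", "D"),
                              length = c(3, 2, 2)))
  pos <- list()
  for (e in tr$edges$name)
    for (i in seq_len(tr$edges$length[branch_index(tr, e)]))
      pos[[length(pos) + 1L]] <- list(branch = e, index = i)
  n <- length(pos)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    D[i, j] <- rearrangement_distance(tr, pos[[i]], pos[[j]])
  expect_equal(D, t(D))
  expect_true(all(D[upper.tri(D)] >= 1L))
  for (k in seq_len(n))
    expect_true(all(D <= outer(D[, k], D[k, ], "+")))
})

test_that("newick round trip preserves topology and lengths", {
  tr <- five_species_tree(c(M = 56, R = 68, MR = 170, QH = 58, H = 28))
  f <- withr::local_tempfile()
  write_rearr_tree(tr, f)
  tr2 <- read_rearr_tree(f)
  ed1 <- tr$edges[order(tr$edges$name), c("parent", "child", "length")]
  ed2 <- tr2$edges[order(tr2$edges$name), c("parent", "child", "length")]
  rownames(ed1) <- rownames(ed2) <- NULL
  expect_equal(ed1, ed2)
})
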