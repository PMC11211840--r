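test_that("mutation matrix error matches its worked values", {
  expect_identical(mutation_matrix_error(diag(2), diag(2)), 0)
  expect_identical(mutation_matrix_error(diag(2), 1 - diag(2)), 1)
  A <- rbind(c(1, 0), c(0, 1)); B <- rbind(c(1, 1), c(0, 1))
  expect_identical(mutation_matrix_error(A, B), 0.25)
  expect_error(mutation_matrix_error(diag(2), diag(3)), "shape")
})

test_that("mutation matrix error is permutation invariant", {
  set.seed(31)
  A <- matrix(rbinom(24, 1, 0.5), 4, 6)
  B <- matrix(rbinom(24, 1, 0.5), 4, 6)
  e <- mutation_matrix_error(A, B)
  pr <- sample(4); pc <- sample(6)
  expect_identical(mutation_matrix_error(A[pr, pc], B[pr, pc]), e)
})

test_that("parent-child distance matches its worked values", {
  path12 <- clone_tree(c(0L, 1L))
  star <- clone_tree(c(0L, 0L))
  path21 <- clone_tree(c(2L, 0L))
  expect_identical(parent_child_distance(path12, path12), 0)
  expect_identical(parent_child_distance(path12, star), 1)
  expect_identical(parent_child_distance(path12, path21), 2)
  expect_error(parent_child_distance(path12,
                                     clone_tree(c(0L, 1L),
                                                labels = list("x", "y"))),
               "universes")
})

test_that("parent-child distance satisfies the metric axioms", {
  set.seed(37)
  for (rep in 1:40) {
    m <- sample(2:6, 1)
    S1 <- clone_tree(random_parent(m))
    S2 <- clone_tree(random_parent(m))
    S3 <- clone_tree(random_parent(m))
    d12 <- parent_child_distance(S1, S2)
    d21 <- parent_child_distance(S2, S1)
    expect_identical(d12, d21)
    expect_identical(parent_child_distance(S1, S1), 0)
    if (d12 == 0) expect_identical(S1$parent, S2$parent)
    d13 <- parent_child_distance(S1, S3)
    d23 <- parent_child_distance(S2, S3)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("distance expands clustered vertices into canonical chains", {
  # chain of clusters sized 2,1,3: 3 vertices but 6 mutation labels
  S <- clone_tree(c(0L, 1L, 2L),
                  labels = list(c("a", "b"), "c", c("d", "e", "f")))
  # identical expanded tree, built raw: a->b->c->d->e->f
  Sraw <- clone_tree(c(0L, 1L, 2L, 3L, 4L, 5L),
                     labels = as.list(c("a", "b", "c", "d", "e", "f")))
  expect_identical(parent_child_distance(S, Sraw), 0)
  expect_identical(length(unlist(S$labels)), 6L)
})

test_that("derive_mutation_matrix binarizes the factorized product", {
  gt <- simulate_instance(8, 3, seed = 5)
  sol <- solve_nppm(gt$F, mu = 0.05)
  M <- derive_mutation_matrix(sol)
  expect_true(all(M %in% c(0L, 1L)))
  expect_identical(dim(M), dim(gt$F))
  expect_identical(M, binarize(sol$Fhat))
})

test_that("max concordant cells: worked examples and ILP = exhaustive", {
  S <- clone_tree(c(0L, 1L))
  U_ok <- rbind(c(1, 1), c(1, 0), c(0, 0))
  expect_identical(max_concordant_cells(U_ok, S, method = "exhaustive"), 3L)
  expect_identical(max_concordant_cells(U_ok, S, method = "ilp"), 3L)
  U_bad <- rbind(c(1, 1), c(0, 1), c(1, 0))
  expect_identical(max_concordant_cells(U_bad, S, method = "exhaustive"), 2L)
  expect_identical(max_concordant_cells(U_bad, S, method = "ilp"), 2L)
  expect_identical(max_concordant_cells(matrix(0L, 4, 2), S,
                                        method = "ilp"), 4L)

  set.seed(41)
  for (rep in 1:10) {
    m <- sample(2:4, 1); n <- sample(4:12, 1)
    S <- clone_tree(random_parent(m))
    U <- matrix(rbinom(n * m, 1, 0.5), n, m)
    expect_identical(max_concordant_cells(U, S, method = "ilp"),
                     max_concordant_cells(U, S, method = "exhaustive"),
                     info = paste("rep", rep))
  }
})

test_that("batch aggregation reports medians and IQRs per combination", {
  reps <- data.frame(
    mutation_matrix_error = c(0, 0.1, 0.2, 0.4),
    parent_child_distance = c(0, 1, 0, 2),
    objective = 0, n_cells = c(10, 10, 20, 20), m_mutations = 3)
  agg <- aggregate_reports(reps)
  expect_identical(nrow(agg), 2L)
  expect_equal(agg$mutation_matrix_error_median, c(0.05, 0.3))
  expect_equal(agg$parent_child_distance_median, c(0.5, 1))
  expect_equal(agg$n_replicates, c(2L, 2L))
})
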