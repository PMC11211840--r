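test_that("worked instances solve to their hand-derived optima", {
  # single mutation
  s1 <- solve_nppm(frequency_matrix(matrix(0.4, 1, 1)), mu = 0.05)
  expect_identical(s1$S$parent, 0L)
  expect_equal(s1$U[1, 1], 0.4, tolerance = 1e-7)
  expect_equal(s1$objective, 0, tolerance = 1e-7)

  # the path is uniquely optimal: the star overshoots the row-sum bound
  s2 <- solve_nppm(frequency_matrix(rbind(c(0.7, 0.5), c(0.3, 0))),
                   mu = 0.05)
  expect_identical(s2$S$parent, c(0L, 1L))
  expect_equal(unname(s2$U), rbind(c(0.2, 0.5), c(0.3, 0)),
               tolerance = 1e-7)
  expect_equal(s2$objective, 0, tolerance = 1e-7)

  # crossing frequencies force the star and an irreducible error of 0.6
  s3 <- solve_nppm(frequency_matrix(rbind(c(0.7, 0.6), c(0.6, 0.7))),
                   mu = 0.05)
  expect_identical(s3$S$parent, c(0L, 0L))
  expect_equal(s3$objective, 0.6, tolerance = 1e-7)
})

test_that("solutions satisfy their structural invariants", {
  for (seed in c(2, 9, 23)) {
    gt <- simulate_instance(12, 4, seed = seed)
    sol <- solve_nppm(gt$F, mu = 0.05)
    # Fhat is the product U B, and the solver's objective matches it
    expect_equal(sol$Fhat, compute_fhat(sol$U, sol$B), tolerance = 1e-9)
    expect_equal(sol$objective, sum(abs(gt$F - sol$Fhat)), tolerance = 1e-9)
    # concordance and sparsity floor
    expect_true(matrix_concordance_check(sol$Uprime, sol$S))
    expect_true(trees_concordant(sol$S, sol$T))
    pos <- sol$U[sol$U > 1e-6]
    expect_true(all(pos >= 0.05 - 1e-6))
    expect_true(all(rowSums(sol$U) <= 1 + 1e-6))
    # exactly one parent per clone (m selected edges)
    expect_identical(length(sol$S$parent), ncol(gt$F))
  }
})

test_that("noiseless instances are recovered exactly", {
  for (seed in c(101, 202)) {
    gt <- simulate_instance(15, 4, seed = seed)
    sol <- solve_nppm(gt$F, mu = 0.05)
    expect_equal(sol$objective, 0, tolerance = 1e-6)
    res <- enppm_feasible_bruteforce(gt$F)
    if (res$n_witnesses == 1L)
      expect_identical(sol$S$parent, gt$S$parent)
  }
})

test_that("objective is monotone in the ancestry graph edge set", {
  gt <- simulate_instance(6, 3, seed = 77)
  # restrict to root edges only (star forced), then allow the full graph
  G_star <- ancestry_graph_from_edges(nppm:::root_edges(3), 3)
  G_full <- build_ancestry_graph_exact(gt$F)
  o_star <- solve_nppm(gt$F, G_star, mu = 0.05)$objective
  o_full <- solve_nppm(gt$F, G_full, mu = 0.05)$objective
  expect_lte(o_full, o_star + 1e-9)
})

test_that("compute_fhat agrees with the clone-tree recursion", {
  set.seed(55)
  for (rep in 1:10) {
    m <- sample(2:5, 1)
    S <- clone_tree(random_parent(m))
    B <- clone_matrix_from_tree(S)
    U <- matrix(runif(3 * m, 0, 1 / m), 3, m)
    Fhat <- compute_fhat(U, B)
    # recursion: fhat[,j] = U[,j] + sum over children of fhat[,child]
    rec <- matrix(0, 3, m)
    for (j in order(colSums(unclass(B)))) {      # smallest subtree first
      kids <- which(S$parent == j)
      rec[, j] <- U[, j] + if (length(kids)) rowSums(rec[, kids, drop = FALSE]) else 0
    }
    expect_equal(Fhat, rec, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_identical(compute_fhat(matrix(0, 2, 2), diag(2)),
                   matrix(0, 2, 2))
})

test_that("degenerate inputs are handled as documented", {
  # mu above every frequency: warned, all-zero mixture
  expect_warning(
    s <- solve_nppm(frequency_matrix(matrix(0.02, 2, 1)), mu = 0.5),
    "mu exceeds")
  expect_true(all(s$U == 0))
  # near-duplicate columns reaching the solver: warned
  F <- frequency_matrix(cbind(c(0.5, 0.2), c(0.5, 0.2)))
  expect_warning(solve_nppm(F, mu = 0.05), "near-duplicates")
  # all-zero column attaches to the root with an all-zero mixture column
  F0 <- frequency_matrix(cbind(c(0.5, 0.4), c(0, 0)))
  s0 <- solve_nppm(F0, mu = 0.05)
  expect_true(all(s0$U[, 2] == 0))
  expect_equal(s0$objective, 0, tolerance = 1e-7)
})

test_that("clustered solve conserves mutation labels", {
  gt <- simulate_instance(10, 3, seed = 12)
  # duplicate one column to force a cluster
  F2 <- cbind(unclass(gt$F), dup = gt$F[, 3])
  colnames(F2) <- c(colnames(gt$F), "mut3b")
  sol <- run_nppm(F = frequency_matrix(F2), mu = 0.05, tau = 0.01)
  expect_identical(sort(unlist(sol$S_expanded$labels)),
                   sort(colnames(F2)))
  expect_identical(sol$S_expanded$m, 3L)
  # no clustering performed: expanded tree is the raw tree
  sol2 <- run_nppm(F = gt$F, mu = 0.05, tau = 0.001)
  expect_identical(sol2$S_expanded$parent, sol2$S$parent)
})
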