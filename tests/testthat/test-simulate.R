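test_that("clone tree simulation is deterministic and well formed", {
  S1 <- simulate_clone_tree(6, seed = 13)
  S2 <- simulate_clone_tree(6, seed = 13)
  expect_identical(S1$parent, S2$parent)
  expect_identical(simulate_clone_tree(1, seed = 1)$parent, 0L)
  expect_true(all(S1$parent < seq_len(6)))  # uniform attachment to earlier
})

test_that("m = 2 star fraction approaches one half", {
  stars <- vapply(1:4000, function(s)
    all(simulate_clone_tree(2, seed = s)$parent == 0L), TRUE)
  expect_gt(mean(stars), 0.45)
  expect_lt(mean(stars), 0.55)
})

test_that("lineage + mixtures are concordant with proportion floors", {
  for (seed in 1:25) {
    m <- sample(2:6, 1)
    S <- simulate_clone_tree(m, seed = seed)
    lt <- simulate_lineage_and_mixtures(S, n = 20, seed = seed)
    expect_true(trees_concordant(S, lt$T), info = paste("seed", seed))
    U <- lt$U
    expect_true(all(rowSums(U) <= 1 + 1e-12))
    expect_true(all(U[U > 0] >= 0.05 - 1e-12))
    expect_true(all(colSums(U > 0) >= 1))  # every clone in some cell
    expect_true(is_perfect_phylogeny(binarize(U)))
    expect_true(matrix_concordance_check(binarize(U), S))
  }
})

test_that("ground truth satisfies the exact model invariants", {
  for (seed in 1:10) {
    gt <- simulate_instance(10, 4, seed = seed)
    expect_equal(gt$F, gt$U %*% unclass(gt$B), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(is_perfect_phylogeny(binarize(gt$F)))
    expect_true(enppm_feasible_bruteforce(gt$F)$feasible,
                info = paste("seed", seed))
  }
})

test_that("simulation is bit-identical under a fixed config", {
  a <- simulate_instance(12, 4, seed = 99)
  b <- simulate_instance(12, 4, seed = 99)
  expect_identical(a$variant, b$variant)
  expect_identical(a$S$parent, b$S$parent)
  expect_identical(a$U, b$U)
})

test_that("read counts follow the beta-binomial moments", {
  F1 <- frequency_matrix(matrix(0.3, 100, 10))
  r <- simulate_reads(F1, coverage_mean = 100, s = 50, seed = 4)
  expect_true(all(r$total >= 1))
  frac <- r$variant / r$total
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.3), 3 * se + 1e-3)
  # boundary frequencies are noiseless
  r0 <- simulate_reads(frequency_matrix(matrix(0, 5, 2)), seed = 1)
  expect_true(all(r0$variant == 0L))
  r1 <- simulate_reads(frequency_matrix(matrix(1, 5, 2)), seed = 1)
  expect_true(all(r1$variant == r1$total))
})

test_that("overdispersion exceeds the binomial at moderate s", {
  F1 <- frequency_matrix(matrix(0.5, 400, 5))
  r <- simulate_reads(F1, coverage_mean = 100, s = 50, seed = 8)
  v_obs <- var(as.vector(r$variant / r$total))
  v_binom <- 0.25 / 100
  expect_gt(v_obs, 1.5 * v_binom)
})

test_that("clone loss perturbs frequencies at the requested rate", {
  gt <- simulate_instance(60, 5, seed = 17)
  expect_identical(apply_clone_loss(gt, 0, seed = 1)$F, gt$F)
  gone <- apply_clone_loss(gt, 1, seed = 1)
  expect_true(all(gone$F == 0))
  pert <- apply_clone_loss(gt, 0.05, seed = 2)
  npos <- sum(gt$F > 0)
  rate <- sum(pert$F == 0 & gt$F > 0) / npos
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / npos) + 0.01)
})

test_that("model violation is detectable at high loss rates", {
  discordant <- 0L
  for (seed in 1:10) {
    gt <- simulate_instance(30, 4, seed = seed + 300)
    pert <- apply_clone_loss(gt, 0.5, seed = seed)
    ok <- tryCatch(
      matrix_concordance_check(binarize(pert$F), pert$S),
      error = function(e) FALSE)
    if (!isTRUE(ok)) discordant <- discordant + 1L
  }
  expect_gt(discordant, 0L)
})

test_that("impossible placements raise an informative error", {
  expect_error(
    simulate_lineage_and_mixtures(simulate_clone_tree(8, seed = 1), n = 2,
                                  seed = 1, min_clade_frac = 0.5),
    "could not place")
})
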