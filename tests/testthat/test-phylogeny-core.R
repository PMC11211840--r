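test_that("three-gamete test matches its definition on worked cases", {
  expect_true(is_perfect_phylogeny(diag(3)))
  expect_false(is_perfect_phylogeny(rbind(c(1, 0), c(0, 1), c(1, 1))))
  expect_true(is_perfect_phylogeny(matrix(0L, 4, 3)))
  expect_error(is_perfect_phylogeny(matrix(c(0, 2), 1)), "binary")
})

test_that("three-gamete test agrees with an independent row-loop oracle", {
  set.seed(42)
  for (rep in 1:60) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    M <- matrix(rbinom(nr * nc, 1, runif(1, 0.2, 0.8)), nr, nc)
    expect_identical(is_perfect_phylogeny(M), pp_oracle(M),
                     info = paste("rep", rep))
  }
})

test_that("clone matrix from tree: worked examples", {
  expect_equal(unclass(clone_matrix_from_tree(clone_tree(c(0L, 0L)))),
               diag(1L, 2))
  expect_equal(unclass(clone_matrix_from_tree(clone_tree(c(0L, 1L)))),
               rbind(c(1L, 0L), c(1L, 1L)))
  expect_equal(unclass(clone_matrix_from_tree(clone_tree(0L))),
               matrix(1L, 1, 1))
  expect_error(clone_tree(c(2L, 1L)), "arborescence")
})

test_that("tree <-> matrix round trip holds for random arborescences", {
  set.seed(7)
  for (rep in 1:50) {
    m <- sample(1:7, 1)
    S <- clone_tree(random_parent(m))
    B <- clone_matrix_from_tree(S)
    expect_true(is_perfect_phylogeny(B))
    expect_identical(clone_tree_from_matrix(B)$parent, S$parent)
  }
})

test_that("lineage tree construction covers the worked examples", {
  # caterpillar: clones on a path, cells (1,0) and (1,1)
  T <- lineage_tree_from_binary_matrix(rbind(c(1, 0), c(1, 1)))
  expect_s3_class(T, "lineage_tree")
  expect_false(anyNA(T$origin))
  # clone 1's origin edge must be on the root path of clone 2's
  expect_true(nppm:::lineage_is_ancestor(T, T$origin[1], T$origin[2]))
  expect_false(nppm:::lineage_is_ancestor(T, T$origin[2], T$origin[1]))

  # identical rows: one annotated path, both cells below it
  T2 <- lineage_tree_from_binary_matrix(rbind(c(1, 1), c(1, 1)))
  expect_identical(T2$origin[1], T2$origin[2])
  expect_identical(T2$leaf_parent[1], T2$leaf_parent[2])

  # all-zero: star below founder
  T3 <- lineage_tree_from_binary_matrix(matrix(0L, 3, 2))
  expect_true(all(T3$leaf_parent == 1L))
  expect_true(all(is.na(T3$origin)))

  expect_error(lineage_tree_from_binary_matrix(rbind(c(1, 0), c(0, 1), c(1, 1))),
               "three-gamete")
})

test_that("tree concordance matches the definition on worked examples", {
  S_path <- clone_tree(c(0L, 1L))
  # T from U' rows (1,0),(1,1): clone 2 below clone 1 -> concordant
  T_ok <- lineage_tree_from_binary_matrix(rbind(c(1, 0), c(1, 1)))
  expect_true(trees_concordant(S_path, T_ok))
  # a cell with clone 2 but not clone 1: U' = {(0,1),(1,0)} is PP but
  # discordant with the path order
  T_bad <- lineage_tree_from_binary_matrix(rbind(c(0, 1), c(1, 0)))
  expect_false(trees_concordant(S_path, T_bad))
  # star clone tree has no ordered pairs: any lineage tree is concordant
  S_star <- clone_tree(c(0L, 0L))
  expect_true(trees_concordant(S_star, T_bad))
  expect_error(trees_concordant(S_path,
                                lineage_tree_from_binary_matrix(diag(3))),
               "m mismatch")
})

test_that("matrix concordance check covers the worked examples", {
  S <- clone_tree(c(0L, 1L))
  expect_true(matrix_concordance_check(rbind(c(1, 1), c(1, 0)), S))
  expect_false(matrix_concordance_check(rbind(c(0, 1)), S))
  expect_true(matrix_concordance_check(matrix(0L, 2, 2), S))
})

test_that("matrix and tree formulations of concordance agree", {
  set.seed(11)
  checked <- 0L
  for (rep in 1:200) {
    m <- sample(2:5, 1); n <- sample(1:5, 1)
    S <- clone_tree(random_parent(m))
    U <- matrix(rbinom(n * m, 1, 0.5), n, m)
    mat <- matrix_concordance_check(U, S)
    if (!is_perfect_phylogeny(U)) {
      expect_false(mat)
      expect_error(lineage_tree_from_binary_matrix(U))
      next
    }
    T <- lineage_tree_from_binary_matrix(U)
    expect_identical(trees_concordant(S, T), mat, info = paste("rep", rep))
    checked <- checked + 1L
  }
  expect_gt(checked, 50L)
})

test_that("frequency matrix validation rejects bad input", {
  expect_error(frequency_matrix(matrix(1.2, 1, 1)), "out of")
  expect_error(frequency_matrix(matrix(0.5, 2, 2),
                                cell_ids = c("a", "a")), "unique")
  F <- frequency_matrix(matrix(runif(6), 2, 3))
  expect_identical(dim(F), c(2L, 3L))
})
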