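#' Mutation matrix error
#'
#' Fraction of entries of the inferred cell-by-mutation presence/absence
#' matrix that disagree with the ground truth; 0 iff the matrices match
#' exactly, 1 iff they are complementary.
#'
#' @param M,Mstar same-shape binary matrices (inferred, truth).
#' @return a number in `[0, 1]`.
#' @examples
#' mutation_matrix_error(diag(2), diag(2))  # 0
#' @export
mutation_matrix_error <- function(M, Mstar) {
  M <- as.matrix(M); Mstar <- as.matrix(Mstar)
  check_binary(M); check_binary(Mstar)
  if (!all(dim(M) == dim(Mstar)))
    stop("mutation matrices must have the same shape")
  mean(M != Mstar)
}

#' Mutation matrix of a solution
#'
#' Binarization of the factorized `Fhat = U B`: entry `(i, j)` is 1 iff the
#' modeled frequency of mutation `j` in cell `i` exceeds the tolerance.
#'
#' @param sol an `"nppm_solution"`.
#' @param tol zero tolerance (default 1e-6).
#' @return binary `n x m` matrix.
#' @export
derive_mutation_matrix <- function(sol, tol = 1e-6) {
  stopifnot(inherits(sol, "nppm_solution"))
  binarize(sol$Fhat, tol = tol)
}

#' Parent-child distance between clone trees
#'
#' Size of the symmetric difference of the two edge sets, normalized by the
#' number of mutations; a metric on clone trees, 0 iff the trees are
#' identical. Edges are compared as (parent label, child label) pairs at
#' the raw-mutation level: a vertex carrying several (clustered) mutations
#' is first expanded into a chain in lexicographic label order.
#'
#' @param S,Sstar [clone_tree()] objects over the same mutation universe.
#' @return non-negative number.
#' @examples
#' parent_child_distance(clone_tree(c(0L, 1L)), clone_tree(c(0L, 0L)))  # 1
#' @export
parent_child_distance <- function(S, Sstar) {
  e1 <- expanded_edge_set(S)
  e2 <- expanded_edge_set(Sstar)
  u1 <- unique(unlist(lapply(S$labels, as.character)))
  u2 <- unique(unlist(lapply(Sstar$labels, as.character)))
  if (!setequal(u1, u2))
    stop("clone trees are over different mutation universes")
  m <- length(u1)
  length(setdiff(e1, e2)) / m + length(setdiff(e2, e1)) / m
}

expanded_edge_set <- function(S) {
  if (!inherits(S, "clone_tree")) S <- clone_tree(S)
  # expand multi-label vertices into chains, lexicographic within a vertex
  first <- character(S$m); last <- character(S$m)
  edges <- character(0)
  for (l in seq_len(S$m)) {
    lab <- sort(as.character(S$labels[[l]]))
    first[l] <- lab[1L]; last[l] <- lab[length(lab)]
    if (length(lab) > 1L)
      edges <- c(edges, paste(lab[-length(lab)], lab[-1L], sep = "\r"))
  }
  for (l in seq_len(S$m)) {
    p <- S$parent[l]
    plab <- if (p == 0L) "0" else last[p]
    edges <- c(edges, paste(plab, first[l], sep = "\r"))
  }
  edges
}

#' Largest concordant subset of cells
#'
#' Given a binarized mixture matrix and a clone tree, the maximum number of
#' rows (cells) that can be kept so that the kept submatrix passes
#' [matrix_concordance_check()] — i.e. it is a perfect phylogeny matrix
#' with ancestor-closed rows. `n` minus the result is the minimum number of
#' cells to remove for a concordant cell lineage tree. Solved exactly as a
#' small integer program (method `"ilp"`) or by exhaustive subset search
#' over distinct violating row patterns (method `"exhaustive"`, the test
#' oracle, `n <= 20`).
#'
#' @param Uprime binary `n x m` matrix, columns = clones of `S`.
#' @param S a [clone_tree()].
#' @param method `"ilp"` or `"exhaustive"`.
#' @param time_limit ILP time limit in seconds.
#' @return integer: the maximum number of concordant cells.
#' @export
max_concordant_cells <- function(Uprime, S, method = c("ilp", "exhaustive"),
                                 time_limit = 60) {
  method <- match.arg(method)
  Uprime <- as.matrix(Uprime)
  check_binary(Uprime)
  if (!inherits(S, "clone_tree")) S <- clone_tree(S)
  m <- S$m
  if (ncol(Uprime) != m) stop("columns of U' must match the clones of S")
  n <- nrow(Uprime)
  # rows violating ancestor closure can never be kept
  anc_ok <- rep(TRUE, n)
  for (b in seq_len(m)) {
    p <- S$parent[b]
    if (p != 0L) anc_ok <- anc_ok & !(Uprime[, b] == 1L & Uprime[, p] == 0L)
  }
  if (method == "exhaustive") {
    if (n > 20L) stop("exhaustive search guarded at n <= 20")
    cand <- which(anc_ok)
    for (k in rev(seq_len(length(cand)))) {
      combs <- utils::combn(cand, k)
      for (ci in seq_len(ncol(combs))) {
        if (is_perfect_phylogeny(Uprime[combs[, ci], , drop = FALSE]))
          return(k)
      }
    }
    return(0L)
  }
  max_concordant_cells_ilp(Uprime, anc_ok, time_limit)
}

max_concordant_cells_ilp <- function(Uprime, anc_ok, time_limit) {
  n <- nrow(Uprime); m <- ncol(Uprime)
  pairs <- if (m >= 2L) t(utils::combn(m, 2L)) else matrix(0L, 0L, 2L)
  npair <- nrow(pairs)
  # vars: keep[i] (n binaries), then y11,y10,y01 per pair
  nv <- n + 3L * npair
  ri <- list(); ci <- list(); vv <- list(); lo <- list(); hi <- list()
  nb <- 0L; blk <- 0L
  push <- function(r, c2, v, l, h) {
    blk <<- blk + 1L
    ri[[blk]] <<- nb + r; ci[[blk]] <<- c2; vv[[blk]] <<- v
    lo[[blk]] <<- l; hi[[blk]] <<- h
    nb <<- nb + length(l)
  }
  # constraints y_d >= keep_i for every row in a pair's pattern class, and
  # y11 + y10 + y01 <= 2 per pair (at most two of the three gametes kept)
  if (npair > 0L) for (k in seq_len(npair)) {
    p <- pairs[k, 1L]; q <- pairs[k, 2L]
    y <- n + 3L * (k - 1L)
    classes <- list(
      which(Uprime[, p] == 1L & Uprime[, q] == 1L),
      which(Uprime[, p] == 1L & Uprime[, q] == 0L),
      which(Uprime[, p] == 0L & Uprime[, q] == 1L))
    for (d in 1:3) {
      rows <- classes[[d]]
      if (length(rows)) {
        nr <- length(rows)
        push(r = rep(seq_len(nr), 2L), c2 = c(rep(y + d, nr), rows),
             v = c(rep(1, nr), rep(-1, nr)), l = rep(0, nr),
             h = rep(Inf, nr))
      }
    }
    push(r = rep(1L, 3L), c2 = y + 1:3, v = rep(1, 3L),
         l = -Inf, h = 2)
  }
  # forbidden rows
  bad <- which(!anc_ok)
  ub <- rep(1, nv)
  ub[bad] <- 0
  obj <- c(rep(-1, n), rep(0, 3L * npair))   # maximize kept cells
  if (nb == 0L) {  # no pairs: only ancestor closure matters
    return(sum(anc_ok))
  }
  model <- milp_model(n_vars = nv, obj = obj, lb = 0, ub = ub,
                      integrality = 1,
                      a_row = unlist(ri), a_col = unlist(ci),
                      a_val = unlist(vv),
                      row_lb = unlist(lo), row_ub = unlist(hi))
  res <- milp_solve(model, time_limit = time_limit)
  if (is.null(res$x)) stop("max_concordant_cells ILP failed: ", res$status)
  as.integer(round(sum(res$x[seq_len(n)] > 0.5)))
}

#' Per-instance evaluation report
#'
#' @param sol an `"nppm_solution"`.
#' @param gt an `"nppm_ground_truth"`.
#' @return one-row data.frame with `mutation_matrix_error`,
#'   `parent_child_distance`, `objective`, `n_cells`, `m_mutations`.
#' @export
evaluate_solution <- function(sol, gt) {
  stopifnot(inherits(sol, "nppm_solution"), inherits(gt, "nppm_ground_truth"))
  data.frame(
    mutation_matrix_error = mutation_matrix_error(derive_mutation_matrix(sol),
                                                  gt$M),
    parent_child_distance = parent_child_distance(sol$S, gt$S),
    objective = sol$objective,
    n_cells = nrow(gt$F),
    m_mutations = ncol(gt$F))
}

#' Aggregate per-instance reports by parameter combination
#'
#' @param reports data.frame of rows from [evaluate_solution()] (stacked
#'   with `rbind`).
#' @return data.frame with one row per `(n_cells, m_mutations)` combination
#'   holding the median and interquartile range of both metrics and the
#'   replicate count.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(all(c("mutation_matrix_error", "parent_child_distance",
                  "n_cells", "m_mutations") %in% names(reports)))
  key <- interaction(reports$n_cells, reports$m_mutations, drop = TRUE)
  agg <- lapply(split(reports, key), function(g) data.frame(
    n_cells = g$n_cells[1L], m_mutations = g$m_mutations[1L],
    n_replicates = nrow(g),
    mutation_matrix_error_median = stats::median(g$mutation_matrix_error),
    mutation_matrix_error_iqr = stats::IQR(g$mutation_matrix_error),
    parent_child_distance_median = stats::median(g$parent_child_distance),
    parent_child_distance_iqr = stats::IQR(g$parent_child_distance)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$n_cells, out$m_mutations), , drop = FALSE]
}
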