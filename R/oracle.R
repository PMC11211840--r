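#' Enumerate the spanning arborescences of an ancestry graph
#'
#' Exhaustive, deterministic enumeration of all spanning arborescences of
#' `G` rooted at 0: every non-root vertex picks one incoming edge, subject
#' to acyclicity. Candidates are explored in lexicographic order of the
#' parent choice per vertex, so the output order is reproducible. Intended
#' as a small-instance oracle; guarded at `m <= 8`.
#'
#' @param G an `"ancestry_graph"` (or edge matrix accepted by it).
#' @param max_m size guard (default 8).
#' @return list of [clone_tree()] objects.
#' @examples
#' G <- build_ancestry_graph_exact(matrix(c(0.6, 0.3), 1))
#' length(enumerate_spanning_arborescences(G))  # 2
#' @export
enumerate_spanning_arborescences <- function(G, max_m = 8L) {
  G <- as_ancestry_graph(G)
  m <- G$m
  if (m > max_m)
    stop(sprintf("enumeration guarded at m <= %d (got m = %d)", max_m, m))
  preds <- lapply(seq_len(m), function(j) sort(G$edges[G$edges[, 2L] == j, 1L]))
  out <- list()
  parent <- integer(m)
  recurse <- function(j) {
    if (j > m) {
      # the incremental walk cannot see cycles through vertices whose parent
      # was still unassigned, so validate the completed assignment
      if (is_arborescence(parent))
        out[[length(out) + 1L]] <<- clone_tree(parent, labels = tree_labels(G))
      return(invisible(NULL))
    }
    for (p in preds[[j]]) {
      # reject if choosing p creates a cycle among already-assigned vertices
      v <- p; cyc <- FALSE
      while (v != 0L) {
        if (v == j) { cyc <- TRUE; break }
        if (v > j) break          # not yet assigned; cannot close a cycle
        v <- parent[v]
      }
      # p > j means p's parent is unassigned: a cycle through p could still
      # be closed later, so re-check acyclicity at completion instead
      if (!cyc) {
        parent[j] <<- p
        recurse(j + 1L)
      }
    }
    parent[j] <<- 0L
    invisible(NULL)
  }
  recurse(1L)
  out
}

tree_labels <- function(G) {
  if (is.null(G$mutation_ids)) as.list(as.character(seq_len(G$m)))
  else as.list(G$mutation_ids)
}

is_arborescence <- function(parent) {
  m <- length(parent)
  for (j in seq_len(m)) {
    v <- j; steps <- 0L
    while (v != 0L) {
      v <- parent[v]; steps <- steps + 1L
      if (steps > m) return(FALSE)
    }
  }
  TRUE
}

as_ancestry_graph <- function(G) {
  if (inherits(G, "ancestry_graph")) return(G)
  ancestry_graph(G, max(G[, 2L]))
}

#' Count spanning arborescences by the directed matrix-tree theorem
#'
#' Determinant of the in-degree Laplacian of `G` with the root row/column
#' removed; independent cross-check for the enumerator.
#'
#' @param G an `"ancestry_graph"`.
#' @return number of spanning arborescences rooted at 0.
#' @export
count_arborescences_matrix_tree <- function(G) {
  G <- as_ancestry_graph(G)
  m <- G$m
  L <- matrix(0, m + 1L, m + 1L)
  for (k in seq_len(nrow(G$edges))) {
    u <- G$edges[k, 1L] + 1L; v <- G$edges[k, 2L] + 1L
    L[u, v] <- L[u, v] - 1
    L[v, v] <- L[v, v] + 1
  }
  round(det(L[-1L, -1L, drop = FALSE]))
}

#' Sum condition for a spanning arborescence
#'
#' The perfect phylogeny mixture feasibility condition: in every cell, each
#' mutation's frequency must cover the summed frequencies of its children in
#' the arborescence. The root frequency is taken as 1, so the root
#' inequality bounds the summed frequency of the root's children by 1.
#'
#' @param F frequency matrix.
#' @param H a [clone_tree()] (the candidate arborescence).
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_sum_condition <- function(F, H) {
  F <- as_freq(F)
  if (!inherits(H, "clone_tree")) H <- clone_tree(H)
  m <- H$m
  if (ncol(F) != m) stop("F and H disagree on the number of mutations")
  child_sum <- child_sums(F, H)
  Fx <- cbind(1, unclass(F))  # column 1 = root, frequency 1 everywhere
  all(Fx >= child_sum - 1e-12)
}

child_sums <- function(F, H) {
  # n x (m+1) matrix: summed child frequencies per vertex 0..m
  m <- H$m
  cs <- matrix(0, nrow(F), m + 1L)
  for (j in seq_len(m)) {
    p <- H$parent[j] + 1L
    cs[, p] <- cs[, p] + F[, j]
  }
  cs
}

#' Strict (exact-factorization) condition for a spanning arborescence
#'
#' Characterizes exact concordant factorizations: for every cell and every
#' mutation vertex, the frequency strictly exceeds the summed child
#' frequencies when positive, and the child frequencies sum to zero when the
#' frequency is zero. Strictness reflects that a clone present in a cell
#' must occupy a positive proportion beyond its children's.
#'
#' @inheritParams satisfies_sum_condition
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_enppm_condition <- function(F, H) {
  F <- as_freq(F)
  if (!inherits(H, "clone_tree")) H <- clone_tree(H)
  if (ncol(F) != H$m) stop("F and H disagree on the number of mutations")
  cs <- child_sums(F, H)[, -1L, drop = FALSE]  # vertices 1..m
  Fm <- unclass(F)
  pos <- Fm > 0
  ok_pos <- all(Fm[pos] > cs[pos] + 1e-12)  # strict inequality
  ok_zero <- all(cs[!pos] <= 1e-12)
  # root inequality (mixture rows sum to <= 1) retained via f_{i,0} = 1
  root_ok <- all(child_sums(F, H)[, 1L] <= 1 + 1e-12)
  ok_pos && ok_zero && root_ok
}

#' Brute-force feasibility of exact concordant factorization
#'
#' A frequency matrix admits an exact factorization `F = UB` with concordant
#' perfect phylogenies iff (i) the binarization of `F` is a perfect
#' phylogeny matrix and (ii) some spanning arborescence of the exact
#' ancestry graph satisfies [satisfies_enppm_condition()]. Enumeration-based
#' oracle for small `m`; returns the first witness in enumeration order.
#'
#' @param F frequency matrix.
#' @param max_m size guard passed to the enumerator.
#' @return list with `feasible` (logical) and `witness` (a [clone_tree()]
#'   or `NULL`), plus `n_witnesses` counting all arborescences that satisfy
#'   the condition.
#' @export
enppm_feasible_bruteforce <- function(F, max_m = 8L) {
  F <- as_freq(F)
  if (!is_perfect_phylogeny(binarize(F)))
    return(list(feasible = FALSE, witness = NULL, n_witnesses = 0L))
  G <- build_ancestry_graph_exact(F)
  arbs <- enumerate_spanning_arborescences(G, max_m = max_m)
  witness <- NULL; nw <- 0L
  for (H in arbs) {
    if (satisfies_enppm_condition(F, H)) {
      nw <- nw + 1L
      if (is.null(witness)) witness <- H
    }
  }
  list(feasible = nw > 0L, witness = witness, n_witnesses = nw)
}
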