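#' Ancestry graph of a frequency matrix (exact rule)
#'
#' The ancestry graph `G` has vertices `0..m` (0 = wild-type root) and a
#' directed edge `(j, j')` iff `j = 0` or `f[i, j] >= f[i, j']` in every
#' cell `i`. Candidate clone trees are exactly the spanning arborescences of
#' `G` rooted at 0. Ties (identical columns) yield edges in both directions;
#' the arborescence constraint later selects one.
#'
#' @param F frequency matrix (coerced with [frequency_matrix()]).
#' @return object of class `"ancestry_graph"`: list with `m` and integer
#'   edge matrix `edges` (`parent`, `child`, 0-based parent vertex), sorted
#'   lexicographically.
#' @examples
#' build_ancestry_graph_exact(matrix(c(0.6, 0.3), 1))  # 0->1, 0->2, 1->2
#' @export
build_ancestry_graph_exact <- function(F) {
  F <- as_freq(F)
  m <- ncol(F)
  edges <- root_edges(m)
  for (j in seq_len(m)) for (jp in seq_len(m)) {
    if (j != jp && all(F[, j] >= F[, jp]))
      edges <- rbind(edges, c(j, jp))
  }
  ancestry_graph(edges, m, colnames(F))
}

root_edges <- function(m) cbind(rep(0L, m), seq_len(m))

#' Assemble an ancestry graph from an explicit edge list
#'
#' @param edges two-column matrix of directed edges `(parent, child)`;
#'   vertex 0 is the root and must reach every mutation.
#' @param m number of mutations.
#' @param mutation_ids optional labels.
#' @return an `"ancestry_graph"`.
#' @export
ancestry_graph_from_edges <- function(edges, m, mutation_ids = NULL) {
  ancestry_graph(edges, m, mutation_ids)
}

ancestry_graph <- function(edges, m, mutation_ids = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child")))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  if (anyDuplicated(edges)) edges <- unique(edges)
  stopifnot(all(edges[, 1L] >= 0L), all(edges[, 2L] >= 1L),
            all(edges[, 1L] != edges[, 2L]))
  out0 <- edges[edges[, 1L] == 0L, 2L]
  if (!setequal(out0, seq_len(m)))
    stop("ancestry graph must contain the edge (0, j) for every mutation j")
  structure(list(edges = edges, m = m, mutation_ids = mutation_ids),
            class = "ancestry_graph")
}

#' @export
print.ancestry_graph <- function(x, ...) {
  cat(sprintf("Ancestry graph: %d mutations + root, %d edges\n",
              x$m, nrow(x$edges)))
  invisible(x)
}

#' Ancestry graph from read counts (noise-robust rules)
#'
#' With noisy read counts the exact dominance rule is too brittle: a single
#' noisy cell deletes a true edge. Two rules are provided. `"tolerance"`
#' keeps edge `(j, j')` iff in every cell with coverage for both mutations
#' `v[i,j]/t[i,j] >= v[i,j']/t[i,j'] - tau`; with `tau = 0` and full
#' coverage it reduces to the exact rule. `"adaptive"` (recommended for
#' beta-binomial-like noise) prunes the edge only when some cell shows a
#' violation larger than `tau` plus `z * kappa` binomial standard errors,
#' where `kappa` inflates the binomial standard error to allow for
#' overdispersion; it likewise reduces to the exact rule as coverage grows
#' and noise vanishes.
#'
#' @param variant,total same-shape non-negative integer matrices with
#'   `variant <= total`; `total[i,j] = 0` marks a cell without coverage,
#'   skipped for comparisons involving mutation `j`.
#' @param tau non-negative frequency tolerance (default 0.05, matching the
#'   default minimum clone abundance).
#' @param method `"tolerance"` or `"adaptive"`.
#' @param z,kappa adaptive-rule multipliers (defaults 3 and 2).
#' @return an `"ancestry_graph"`.
#' @export
build_ancestry_graph_robust <- function(variant, total, tau = 0.05,
                                        method = c("tolerance", "adaptive"),
                                        z = 3, kappa = 2) {
  method <- match.arg(method)
  ct <- check_counts(variant, total)
  variant <- ct$variant; total <- ct$total
  if (tau < 0) stop("'tau' must be >= 0")
  m <- ncol(variant)
  Fh <- variant / ifelse(total == 0L, 1L, total)
  covered <- total > 0L
  se2 <- Fh * (1 - Fh) / pmax(total, 1L)
  edges <- root_edges(m)
  for (j in seq_len(m)) for (jp in seq_len(m)) {
    if (j == jp) next
    use <- covered[, j] & covered[, jp]
    if (!any(use)) { edges <- rbind(edges, c(j, jp)); next }
    d <- Fh[use, jp] - Fh[use, j]
    slack <- if (method == "tolerance") tau
             else tau + z * kappa * sqrt(se2[use, j] + se2[use, jp])
    if (all(d <= slack)) edges <- rbind(edges, c(j, jp))
  }
  ancestry_graph(edges, m, colnames(variant))
}

check_counts <- function(variant, total) {
  variant <- as.matrix(variant); total <- as.matrix(total)
  if (!all(dim(variant) == dim(total)))
    stop("'variant' and 'total' must have the same shape")
  if (anyNA(variant) || anyNA(total)) stop("count matrices must not contain NA")
  if (any(variant < 0L) || any(total < 0L)) stop("counts must be non-negative")
  bad <- which(variant > total, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("variant > total at cell %d, mutation %d", bad[1, 1], bad[1, 2]))
  list(variant = variant, total = total)
}

#' Pre-cluster mutations with indistinguishable frequency columns
#'
#' Mutations whose frequency columns agree within `tau` in every cell cannot
#' be ordered by the data and would violate the minimum-abundance constraint
#' if modeled as separate clones; they are merged before solving. Clusters
#' are the connected components of the mutual-edge graph (both `(j, j')` and
#' `(j', j)` pass the per-cell tolerance test); the merged column is the
#' per-cell mean of the members.
#'
#' @param F frequency matrix.
#' @param tau per-cell tolerance (default 0.05).
#' @return list with `F` (clustered frequency matrix, one column per
#'   cluster, named after the first member) and `clusters` (named list of
#'   member mutation ids).
#' @export
cluster_mutations <- function(F, tau = 0.05) {
  F <- as_freq(F)
  m <- ncol(F)
  comp <- seq_len(m)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (m > 1L) for (j in seq_len(m - 1L)) for (jp in (j + 1L):m) {
    if (all(abs(F[, j] - F[, jp]) <= tau)) {
      rj <- find(j); rp <- find(jp)
      if (rj != rp) comp[max(rj, rp)] <- min(rj, rp)
    }
  }
  roots <- vapply(seq_len(m), find, 1L)
  ids <- colnames(F)
  uroot <- sort(unique(roots))
  members <- lapply(uroot, function(r) ids[roots == r])
  names(members) <- ids[uroot]
  vals <- vapply(uroot, function(r) rowMeans(F[, roots == r, drop = FALSE]),
                 numeric(nrow(F)))
  if (nrow(F) == 1L) vals <- matrix(vals, nrow = 1L)
  Fc <- frequency_matrix(vals, cell_ids = rownames(F), mutation_ids = ids[uroot])
  list(F = Fc, clusters = members)
}

#' Write an ancestry graph as a two-column edge list
#'
#' @param G an `"ancestry_graph"`.
#' @param path output TSV path (`parent_index`, `child_index`; 0 = root).
#' @export
write_ancestry_graph <- function(G, path) {
  utils::write.table(G$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("parent_index", "child_index"))
  invisible(path)
}

#' Read an ancestry graph edge list
#'
#' @param path TSV written by [write_ancestry_graph()].
#' @param m number of mutations (default: max vertex index in the file).
#' @return an `"ancestry_graph"`.
#' @export
read_ancestry_graph <- function(path, m = NULL) {
  e <- utils::read.table(path, sep = "\t", header = TRUE)
  if (is.null(m)) m <- max(e[[2L]])
  ancestry_graph(as.matrix(e), m)
}
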