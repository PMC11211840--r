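#' End-to-end inference from frequencies or read counts
#'
#' Convenience pipeline: optionally pre-cluster indistinguishable mutations,
#' build the ancestry graph (exact rule for a frequency matrix, adaptive
#' noise-robust rule when read counts are supplied), solve the nested
#' perfect phylogeny mixture program, and expand clustered labels back onto
#' the clone tree.
#'
#' @param F frequency matrix (ignored when counts are given).
#' @param variant,total optional read-count matrices; when present, `F` is
#'   derived as `variant/total` and the ancestry graph uses the adaptive
#'   robust rule.
#' @param mu minimum clone proportion (default 0.05).
#' @param tau clustering/graph tolerance (default 0.05).
#' @param cluster pre-cluster near-identical mutation columns (default TRUE).
#' @param time_limit solver limit in seconds (default 600).
#' @param verbose print progress.
#' @return an `"nppm_solution"` with extra fields `clusters` (the cluster
#'   map) and `S_expanded` (clone tree with full mutation labels).
#' @export
run_nppm <- function(F = NULL, variant = NULL, total = NULL, mu = 0.05,
                     tau = 0.05, cluster = TRUE, time_limit = 600,
                     verbose = FALSE) {
  have_counts <- !is.null(variant) && !is.null(total)
  if (!have_counts && is.null(F))
    stop("supply either F or both variant and total")
  if (have_counts) {
    ct <- check_counts(variant, total)
    variant <- ct$variant; total <- ct$total
    Fv <- variant / ifelse(total == 0L, 1L, total)
    if (is.null(rownames(Fv))) rownames(Fv) <- paste0("cell", seq_len(nrow(Fv)))
    F <- frequency_matrix(Fv)
  } else {
    F <- as_freq(F)
  }
  clusters <- NULL
  if (cluster) {
    cl <- cluster_mutations(F, tau = tau)
    clusters <- cl$clusters
    if (ncol(cl$F) < ncol(F)) {
      if (verbose)
        message(sprintf("clustered %d mutations into %d clones",
                        ncol(F), ncol(cl$F)))
      keep <- match(colnames(cl$F), colnames(F))
      if (have_counts) {  # aggregate counts over cluster members
        variant <- vapply(clusters, function(mem)
          rowSums(variant[, mem, drop = FALSE]), numeric(nrow(F)))
        total <- vapply(clusters, function(mem)
          rowSums(total[, mem, drop = FALSE]), numeric(nrow(F)))
        if (nrow(F) == 1L) {
          variant <- matrix(variant, 1L); total <- matrix(total, 1L)
        }
        colnames(variant) <- colnames(total) <- names(clusters)
      }
      F <- cl$F
    }
  }
  G <- if (have_counts)
    build_ancestry_graph_robust(variant, total, tau = tau,
                                method = "adaptive")
  else build_ancestry_graph_exact(F)
  sol <- solve_nppm(F, G, mu = mu, time_limit = time_limit,
                    verbose = verbose)
  sol$clusters <- clusters
  sol$S_expanded <- collapse_clone_tree(sol, clusters)
  sol
}
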