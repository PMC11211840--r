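#' Three-gamete test for a perfect phylogeny matrix
#'
#' A binary matrix is a perfect phylogeny matrix iff no pair of columns
#' exhibits all three row patterns (1,0), (0,1) and (1,1); equivalently, the
#' column supports form a laminar family (pairwise nested or disjoint).
#'
#' @param M binary matrix (any shape); rows are taxa, columns characters.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_perfect_phylogeny(diag(3))                       # TRUE
#' is_perfect_phylogeny(rbind(c(1,0), c(0,1), c(1,1))) # FALSE
#' @export
is_perfect_phylogeny <- function(M) {
  M <- as.matrix(M)
  check_binary(M)
  m <- ncol(M)
  if (m < 2L) return(TRUE)
  Mi <- matrix(as.numeric(M), nrow(M), m)
  both <- crossprod(Mi)              # pattern (1,1) counts per pair
  ones <- colSums(Mi)
  for (p in seq_len(m - 1L)) {
    for (q in (p + 1L):m) {
      n11 <- both[p, q]
      n10 <- ones[p] - n11
      n01 <- ones[q] - n11
      if (n11 > 0 && n10 > 0 && n01 > 0) return(FALSE)
    }
  }
  TRUE
}

#' Cell lineage tree from the binarized mixture matrix
#'
#' Builds the rooted cell lineage tree encoded by a binary cell-by-clone
#' matrix `U'` that passes the three-gamete test. Clones are characters and
#' cells are leaves: clones with identical columns originate together on one
#' edge; distinct column supports are nested or disjoint and therefore form
#' a tree below the wild-type founder root. Each cell hangs as a leaf under
#' the vertex of its (unique) maximal clone group; cells with no mutated
#' clones attach directly below the founder.
#'
#' @param Uprime binary `n x m` matrix (cells in rows, clones in columns).
#' @param cell_ids optional `n` cell labels (default rownames or `cell<i>`).
#' @return object of class `"lineage_tree"` with fields
#'   \describe{
#'     \item{parent}{integer vector over internal vertices; `parent[1] = 0`
#'       marks the founder root.}
#'     \item{origin}{integer vector of length `m`: the vertex whose incoming
#'       edge hosts clone `l`'s origin, or `NA` for a clone in no cell.}
#'     \item{leaf_parent}{integer vector of length `n`: the internal vertex
#'       each cell hangs below.}
#'     \item{cell_ids}{the cell labels.}
#'   }
#' @export
lineage_tree_from_binary_matrix <- function(Uprime, cell_ids = NULL) {
  Uprime <- as.matrix(Uprime)
  check_binary(Uprime)
  n <- nrow(Uprime); m <- ncol(Uprime)
  if (is.null(cell_ids)) cell_ids <- rownames(Uprime)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (!is_perfect_phylogeny(Uprime))
    stop("binarized mixture matrix fails the three-gamete condition; no cell lineage tree exists")
  # group clones by identical columns
  key <- apply(Uprime, 2L, paste, collapse = "")
  nonzero <- colSums(Uprime) > 0L
  groups <- split(seq_len(m)[nonzero], key[nonzero])
  gsup <- lapply(groups, function(g) which(Uprime[, g[1L]] == 1L))
  sizes <- vapply(gsup, length, 1L)
  ord <- order(-sizes, vapply(groups, function(g) min(g), 1L))
  groups <- groups[ord]; gsup <- gsup[ord]; sizes <- sizes[ord]
  ng <- length(groups)
  # vertex 1 = founder root; vertices 1+k = group k (in decreasing support)
  parent <- integer(ng + 1L)
  parent[1L] <- 0L
  for (k in seq_len(ng)) {
    p <- 1L
    if (k > 1L) for (k2 in (k - 1L):1L) {
      if (all(gsup[[k]] %in% gsup[[k2]])) { p <- k2 + 1L; break }
    }
    parent[k + 1L] <- p
  }
  origin <- rep(NA_integer_, m)
  for (k in seq_len(ng)) origin[groups[[k]]] <- k + 1L
  # each cell's clone set is a chain of nested groups; attach below deepest
  leaf_parent <- rep(1L, n)
  for (k in seq_len(ng)) leaf_parent[gsup[[k]]] <- k + 1L  # later = smaller = deeper
  structure(list(parent = parent, origin = origin, leaf_parent = leaf_parent,
                 cell_ids = cell_ids, m = m),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("Cell lineage tree: %d cells, %d internal vertices, %d clone origins\n",
              length(x$cell_ids), length(x$parent), sum(!is.na(x$origin))))
  invisible(x)
}

lineage_is_ancestor <- function(T, v, w) {
  # is internal vertex v an ancestor of (or equal to) internal vertex w?
  while (!is.na(w) && w != 0L) {
    if (w == v) return(TRUE)
    w <- T$parent[w]
  }
  FALSE
}

#' Concordance of a clone tree and a cell lineage tree
#'
#' The two trees are concordant iff the partial order the lineage tree
#' induces on clones (by the placement of their origin edges) extends the
#' clone-tree order: whenever clone `a` is an ancestor of clone `b` in `S`,
#' the origin edge of `a` lies on the root path of the origin edge of `b`.
#' Clones originating on the same lineage edge are taken as ordered by `S`
#' and hence concordant.
#'
#' @param S a [clone_tree()].
#' @param T a `"lineage_tree"` over the same `m` clones.
#' @return `TRUE` or `FALSE`.
#' @export
trees_concordant <- function(S, T) {
  if (!inherits(S, "clone_tree")) S <- clone_tree(S)
  if (!inherits(T, "lineage_tree")) stop("'T' must be a lineage_tree")
  if (S$m != T$m) stop("clone sets of the two trees differ (m mismatch)")
  anc <- clone_tree_ancestry(S)
  for (b in seq_len(S$m)) {
    as_ <- which(anc[, b])
    if (length(as_) == 0L) next
    ob <- T$origin[b]
    if (is.na(ob)) next  # clone absent from every cell: nothing to order
    for (a in as_) {
      oa <- T$origin[a]
      if (is.na(oa)) return(FALSE)  # descendant present but ancestor nowhere
      if (!lineage_is_ancestor(T, oa, ob)) return(FALSE)
    }
  }
  TRUE
}

#' Matrix form of the concordance check
#'
#' Equivalent to building the lineage tree from `U'` and testing concordance
#' with `S`: `U'` must pass the three-gamete test and every row's clone set
#' must be ancestor-closed in `S` (a cell containing a clone contains all of
#' the clone's ancestors).
#'
#' @param Uprime binary `n x m` matrix, columns indexed by the clones of `S`.
#' @param S a [clone_tree()].
#' @return `TRUE` or `FALSE`.
#' @export
matrix_concordance_check <- function(Uprime, S) {
  Uprime <- as.matrix(Uprime)
  check_binary(Uprime)
  if (!inherits(S, "clone_tree")) S <- clone_tree(S)
  if (ncol(Uprime) != S$m) stop("columns of U' must match the clones of S")
  if (!is_perfect_phylogeny(Uprime)) return(FALSE)
  for (b in seq_len(S$m)) {
    p <- S$parent[b]
    if (p == 0L) next
    if (any(Uprime[, b] == 1L & Uprime[, p] == 0L)) return(FALSE)
  }
  TRUE
}
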