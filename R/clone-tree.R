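#' Construct a mitochondrial clone tree
#'
#' A clone tree is a rooted arborescence on vertices `0, 1, ..., m`, where
#' vertex 0 is the wild-type root and vertex `j >= 1` is the mitochondrial
#' clone created by mutation `j`: under the infinite sites assumption each
#' mutation occurs exactly once, on the edge into its clone. After mutation
#' clustering a vertex may carry several mutation labels (a multi-mutation
#' edge); `labels` then holds one character vector per clone.
#'
#' @param parent integer vector of length `m`; `parent[j]` is the parent
#'   vertex of clone `j`, a value in `0:(j's predecessors)`, i.e. in `0:m`,
#'   never `j` itself.
#' @param labels optional list (length `m`) of character vectors of mutation
#'   identifiers per clone; defaults to `as.character(1:m)` singletons.
#' @return object of class `"clone_tree"`.
#' @examples
#' path2 <- clone_tree(c(0L, 1L))   # 0 -> 1 -> 2
#' star2 <- clone_tree(c(0L, 0L))   # 0 -> 1, 0 -> 2
#' @export
clone_tree <- function(parent, labels = NULL) {
  parent <- as.integer(parent)
  m <- length(parent)
  if (m < 1L) stop("clone tree needs at least one clone")
  if (anyNA(parent) || any(parent < 0L) || any(parent > m))
    stop("'parent' entries must be vertices in 0..m")
  if (any(parent == seq_len(m))) stop("self-loop in clone tree")
  # walk to root from every vertex; detect cycles / disconnection
  for (j in seq_len(m)) {
    v <- j; steps <- 0L
    while (v != 0L) {
      v <- parent[v]
      steps <- steps + 1L
      if (steps > m) stop("'parent' does not describe an arborescence rooted at 0")
    }
  }
  if (is.null(labels)) labels <- as.list(as.character(seq_len(m)))
  if (length(labels) != m) stop("'labels' must have one entry per clone")
  structure(list(parent = parent, m = m, labels = labels), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("Clone tree on %d clones (root = 0)\n", x$m))
  lab <- vapply(x$labels, function(l) paste(l, collapse = ","), "")
  cat(paste0("  ", x$parent, " -> ", seq_len(x$m), "  [", lab, "]\n"), sep = "")
  invisible(x)
}

#' Edge set of a clone tree
#'
#' @param S a [clone_tree()].
#' @return two-column integer matrix `(parent, child)`, one row per clone.
#' @export
clone_tree_edges <- function(S) {
  cbind(parent = S$parent, child = seq_len(S$m))
}

#' Ancestor indicator of a clone tree
#'
#' @param S a [clone_tree()].
#' @return `m x m` logical matrix; entry `(a, b)` is `TRUE` iff clone `a` is
#'   a strict ancestor of clone `b` in `S`.
#' @export
clone_tree_ancestry <- function(S) {
  m <- S$m
  anc <- matrix(FALSE, m, m)
  for (b in seq_len(m)) {
    v <- S$parent[b]
    while (v != 0L) {
      anc[v, b] <- TRUE
      v <- S$parent[v]
    }
  }
  anc
}

#' Clone matrix of a clone tree
#'
#' Row `l` of the clone matrix `B` marks exactly the mutations on the path
#' from the root to clone `l`; `B` is a perfect phylogeny matrix.
#'
#' @param S a [clone_tree()].
#' @return `m x m` integer 0/1 matrix of class `"clone_matrix"` (clones in
#'   rows, mutations in columns).
#' @examples
#' clone_matrix_from_tree(clone_tree(c(0L, 1L)))  # rows (1,0), (1,1)
#' @export
clone_matrix_from_tree <- function(S) {
  if (!inherits(S, "clone_tree")) S <- clone_tree(S)
  m <- S$m
  B <- diag(1L, m)
  for (l in seq_len(m)) {
    v <- S$parent[l]
    while (v != 0L) {
      B[l, v] <- 1L
      v <- S$parent[v]
    }
  }
  structure(B, class = c("clone_matrix", class(B)))
}

#' Clone tree from a clone matrix
#'
#' Inverse of [clone_matrix_from_tree()]: recovers the arborescence whose
#' root-to-clone paths reproduce the rows of `B`. The parent of clone `l` is
#' the mutation in row `l` (other than `l`) with the largest row weight,
#' i.e. the nearest strict ancestor.
#'
#' @param B binary `m x m` matrix with `B[l, l] = 1` for all `l`.
#' @return a [clone_tree()].
#' @export
clone_tree_from_matrix <- function(B) {
  B <- as.matrix(B)
  check_binary(B)
  m <- nrow(B)
  if (ncol(B) != m) stop("clone matrix must be square (clones x mutations)")
  if (any(diag(B) != 1L)) stop("clone l must carry its own mutation l")
  if (!is_perfect_phylogeny(B)) stop("clone matrix is not a perfect phylogeny matrix")
  depth <- rowSums(B)
  parent <- integer(m)
  for (l in seq_len(m)) {
    on_path <- setdiff(which(B[l, ] == 1L), l)
    if (length(on_path) == 0L) { parent[l] <- 0L; next }
    # the ancestors of l on its root path, deepest one is the parent
    d <- depth[on_path]
    parent[l] <- on_path[which.max(d)]
  }
  clone_tree(parent)
}

check_binary <- function(M) {
  if (!is.matrix(M)) stop("expected a matrix")
  if (anyNA(M) || !all(M == 0L | M == 1L)) stop("matrix must be binary (0/1)")
  invisible(M)
}
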