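#' Construct a cell-by-mutation frequency matrix
#'
#' The frequency matrix `F` holds, for each sequenced cell (row) and each
#' mitochondrial mutation (column), the heteroplasmic fraction: the fraction
#' of mitochondrial genomes in that cell carrying the mutation. Entries must
#' lie in `[0, 1]`.
#'
#' @param values numeric matrix, `n` cells by `m` mutations.
#' @param cell_ids character vector of `n` unique cell labels. Defaults to
#'   existing rownames or `cell1..celln`.
#' @param mutation_ids character vector of `m` unique mutation labels.
#'   Defaults to existing colnames or `mut1..mutm`.
#' @return a numeric matrix of class `"nppm_freq"` with row/column names set.
#' @examples
#' F <- frequency_matrix(rbind(c(0.7, 0.5), c(0.3, 0)))
#' @export
frequency_matrix <- function(values, cell_ids = NULL, mutation_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  n <- nrow(values); m <- ncol(values)
  if (n < 1L || m < 1L) stop("frequency matrix needs n >= 1 cells and m >= 1 mutations")
  if (anyNA(values)) stop("frequency matrix entries must not be NA")
  bad <- which(values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("frequency out of [0,1] at cell %d, mutation %d (value %g)",
                 bad[1, 1], bad[1, 2], values[bad[1, 1], bad[1, 2]]))
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (is.null(mutation_ids)) mutation_ids <- colnames(values)
  if (is.null(mutation_ids)) mutation_ids <- paste0("mut", seq_len(m))
  if (length(cell_ids) != n || anyDuplicated(cell_ids))
    stop("'cell_ids' must be n unique labels")
  if (length(mutation_ids) != m || anyDuplicated(mutation_ids))
    stop("'mutation_ids' must be m unique labels")
  dimnames(values) <- list(cell_ids, mutation_ids)
  class(values) <- c("nppm_freq", class(values))
  values
}

#' @export
print.nppm_freq <- function(x, ...) {
  cat(sprintf("Frequency matrix: %d cells x %d mutations\n", nrow(x), ncol(x)))
  y <- x[seq_len(min(6L, nrow(x))), , drop = FALSE]
  print(unclass(y), digits = 3)
  if (nrow(x) > 6L) cat(sprintf("... and %d more cells\n", nrow(x) - 6L))
  invisible(x)
}

as_freq <- function(F) {
  if (inherits(F, "nppm_freq")) return(F)
  frequency_matrix(as.matrix(F))
}

#' Binarize a non-negative matrix
#'
#' Entries strictly above `tol` map to 1L, all others to 0L. Used to obtain
#' the binarization U' of a mixture matrix and the mutation matrix from a
#' fitted frequency matrix; the tolerance absorbs solver round-off.
#'
#' @param x numeric matrix.
#' @param tol threshold below which an entry counts as zero (default `1e-6`).
#' @return integer 0/1 matrix of the same shape and dimnames.
#' @export
binarize <- function(x, tol = 1e-6) {
  b <- matrix(as.integer(x > tol), nrow(x), ncol(x), dimnames = dimnames(x))
  b
}
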