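# Readers and writers for all artifacts. Matrices are CSV with a header of
# mutation ids and a first column of cell ids (cells in rows, mutations in
# columns); trees are TSV edge lists; lineage trees are Newick; summaries
# are JSON.

#' Read a frequency matrix from CSV/TSV
#'
#' @param path file with a header row of mutation ids and first column of
#'   cell ids; separator inferred from the extension (`.tsv` = tab).
#' @return a [frequency_matrix()].
#' @export
read_frequency_matrix <- function(path) {
  df <- read_matrix_file(path)
  vals <- as.matrix(df$values)
  if (!is.numeric(vals)) stop_bad_numeric(vals, path)
  bad <- which(vals < 0 | vals > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s: entry at data row %d, column '%s' is %g, outside [0,1]",
                 path, bad[1, 1], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  frequency_matrix(vals, cell_ids = df$cell_ids,
                   mutation_ids = colnames(df$values))
}

read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop(path, ": parse error: ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop(path, ": expected a header of mutation ids and a first column of cell ids")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop(path, ": duplicate cell ids")
  if (anyDuplicated(colnames(df)[-1L]))  # before `[.data.frame` mangles them
    stop(path, ": duplicate mutation ids")
  vals <- df[, -1L, drop = FALSE]
  list(cell_ids = ids, values = vals)
}

stop_bad_numeric <- function(vals, path) {
  bad <- which(!vapply(as.data.frame(vals), is.numeric, TRUE))
  stop(sprintf("%s: column '%s' is not numeric", path,
               colnames(vals)[bad[1L]]))
}

#' Write a matrix with cell-id first column
#'
#' @param x matrix with dimnames.
#' @param path output path (`.tsv` for tab separation).
#' @export
write_cell_matrix <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(cell_id = rownames(x), as.data.frame(unclass(x),
                   check.names = FALSE), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variant/total count matrices
#'
#' @param variant_path,total_path CSV/TSV files in the layout of
#'   [read_frequency_matrix()] holding non-negative integers with
#'   `variant <= total`.
#' @return list with integer matrices `variant`, `total`, the derived
#'   frequency matrix `F` (0/0 treated as 0) and logical `mask` marking
#'   entries without coverage.
#' @export
read_count_matrices <- function(variant_path, total_path) {
  v <- read_matrix_file(variant_path)
  t <- read_matrix_file(total_path)
  vm <- as.matrix(v$values); tm <- as.matrix(t$values)
  if (!all(dim(vm) == dim(tm)))
    stop("count matrices differ in shape: ", variant_path, " vs ", total_path)
  if (!identical(v$cell_ids, t$cell_ids) ||
      !identical(colnames(vm), colnames(tm)))
    stop("count matrices have different cell or mutation labels")
  if (any(vm != round(vm)) || any(tm != round(tm)))
    stop("count matrices must be integer")
  bad <- which(vm > tm, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("variant > total for cell '%s', mutation '%s'",
                 v$cell_ids[bad[1, 1]], colnames(vm)[bad[1, 2]]))
  rownames(vm) <- rownames(tm) <- v$cell_ids
  ct <- check_counts(vm, tm)
  mask <- tm == 0L
  Fv <- vm / ifelse(mask, 1L, tm)
  list(variant = ct$variant, total = ct$total,
       F = frequency_matrix(Fv, cell_ids = v$cell_ids,
                            mutation_ids = colnames(vm)),
       mask = mask)
}

#' Newick string of a cell lineage tree
#'
#' Leaves are the sequenced cells (labels = cell ids); internal vertices
#' are unlabeled ancestral cells. Unary vertices (single-child chains) are
#' preserved.
#'
#' @param T a `"lineage_tree"`.
#' @return Newick string, semicolon-terminated.
#' @export
lineage_newick <- function(T) {
  nv <- length(T$parent)
  kids <- vector("list", nv)
  for (v in seq_len(nv)[-1L]) kids[[T$parent[v]]] <- c(kids[[T$parent[v]]], v)
  cells <- vector("list", nv)
  for (i in seq_along(T$cell_ids))
    cells[[T$leaf_parent[i]]] <- c(cells[[T$leaf_parent[i]]], T$cell_ids[i])
  rec <- function(v) {
    parts <- c(vapply(kids[[v]], rec, ""), unlist(cells[[v]]))
    if (length(parts) == 0L) return(sprintf("v%d", v))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(1L), ";")
}

#' Write a clone tree as an edge-list TSV
#'
#' Columns: parent vertex, child vertex (0 = wild-type root) and the
#' comma-joined mutation labels of the child clone.
#'
#' @param S a [clone_tree()].
#' @param path output path.
#' @export
write_clone_tree <- function(S, path) {
  lab <- vapply(S$labels, function(l) paste(l, collapse = ","), "")
  df <- data.frame(parent = S$parent, child = seq_len(S$m), labels = lab)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clone tree edge-list TSV
#'
#' @param path file written by [write_clone_tree()].
#' @return a [clone_tree()].
#' @export
read_clone_tree <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  parent <- integer(max(df$child))
  parent[df$child] <- df$parent
  labels <- as.list(as.character(df$labels))
  labels <- lapply(labels, function(s) strsplit(s, ",", fixed = TRUE)[[1L]])
  clone_tree(parent, labels = labels[order(df$child)])
}

#' Write a full solution to a directory
#'
#' Emits `U.csv`, `B.csv`, `clone_tree.tsv`, `lineage.nwk` and
#' `summary.json` (objective, status, mu, runtime).
#'
#' @param sol an `"nppm_solution"`.
#' @param outdir output directory (created if needed).
#' @param seed optional seed to record in the summary.
#' @return invisibly, the directory.
#' @export
write_solution <- function(sol, outdir, seed = NULL) {
  stopifnot(inherits(sol, "nppm_solution"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_cell_matrix(sol$U, file.path(outdir, "U.csv"))
  Bdf <- data.frame(clone = rownames(sol$B),
                    as.data.frame(unclass(sol$B), check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(Bdf, file.path(outdir, "B.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  write_clone_tree(sol$S, file.path(outdir, "clone_tree.tsv"))
  writeLines(lineage_newick(sol$T), file.path(outdir, "lineage.nwk"))
  jsonlite::write_json(
    list(objective = sol$objective, status = sol$status, mu = sol$mu,
         runtime_seconds = sol$runtime, seed = seed),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(outdir)
}

#' Write a simulated ground truth to a directory
#'
#' @param gt an `"nppm_ground_truth"`.
#' @param outdir output directory.
#' @return invisibly, the directory.
#' @export
write_ground_truth <- function(gt, outdir) {
  stopifnot(inherits(gt, "nppm_ground_truth"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_cell_matrix(gt$F, file.path(outdir, "F.csv"))
  write_cell_matrix(gt$Fobs, file.path(outdir, "F_observed.csv"))
  write_cell_matrix(gt$variant, file.path(outdir, "variant.csv"))
  write_cell_matrix(gt$total, file.path(outdir, "total.csv"))
  write_cell_matrix(gt$U, file.path(outdir, "U.csv"))
  write_cell_matrix(gt$M, file.path(outdir, "mutation_matrix.csv"))
  write_clone_tree(gt$S, file.path(outdir, "clone_tree.tsv"))
  writeLines(lineage_newick(gt$T), file.path(outdir, "lineage.nwk"))
  jsonlite::write_json(gt$config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
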