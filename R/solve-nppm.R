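#' Solve the nested perfect phylogeny mixture problem exactly
#'
#' Finds a mixture matrix `U` and clone matrix `B` minimizing the L1 error
#' `|F - UB|` such that `B` and the binarization `U'` of `U` are perfect
#' phylogeny matrices and the corresponding clone tree and cell lineage tree
#' are concordant. The clone tree is constrained to be a spanning
#' arborescence of the ancestry graph `G`; every clone present in a cell
#' must have proportion at least `mu` there (sparsity floor).
#'
#' The mixed-integer program has one binary per ancestry-graph edge (clone
#' tree), one binary per cell/clone pair (the binarization `U'`), three
#' binaries per clone pair (three-gamete forbidding for `U'`), and
#' continuous blocks for `U`, the fitted frequencies and the L1 slacks.
#' Tie-breaking among co-optimal solutions is determinized by a fixed
#' variable order and the single-threaded deterministic solver.
#'
#' @param F frequency matrix (`n` cells by `m` mutations).
#' @param G ancestry graph; default [build_ancestry_graph_exact()] of `F`.
#' @param mu minimum clone proportion in a cell (default 0.05).
#' @param time_limit solver wall-clock limit in seconds (default 600). When
#'   the limit is reached the best incumbent found is returned with status
#'   `"limit_reached"`.
#' @param mip_rel_gap relative optimality gap (default 0, exact).
#' @param verbose print solver output.
#' @return object of class `"nppm_solution"`: list with `U`, `Uprime`, `B`,
#'   `S` (clone tree), `T` (cell lineage tree), `Fhat = U %*% B`,
#'   `objective` (recomputed L1 error), `solver_objective`, `status`, `mu`,
#'   `runtime`.
#' @examples
#' \donttest{
#' F <- frequency_matrix(rbind(c(0.7, 0.5), c(0.3, 0)))
#' sol <- solve_nppm(F, mu = 0.05)
#' sol$S$parent          # path 0 -> 1 -> 2
#' }
#' @export
solve_nppm <- function(F, G = NULL, mu = 0.05, time_limit = 600,
                       mip_rel_gap = 0, verbose = FALSE) {
  F <- as_freq(F)
  n <- nrow(F); m <- ncol(F)
  if (mu < 0 || mu > 1) stop("'mu' must be in [0, 1]")
  if (is.null(G)) G <- build_ancestry_graph_exact(F)
  if (!inherits(G, "ancestry_graph")) G <- as_ancestry_graph(G)
  if (G$m != m) stop("ancestry graph and frequency matrix disagree on m")
  if (mu > max(F))
    warning("mu exceeds every observed frequency; the optimal mixture is all-zero")
  warn_near_duplicate_columns(F)

  model <- build_nppm_model(unclass(F), G, mu)
  res <- milp_solve(model$model, time_limit = time_limit,
                    mip_rel_gap = mip_rel_gap, verbose = verbose)
  if (is.null(res$x))
    stop("solver returned no feasible solution (status: ", res$status, ")")
  extract_solution(F, G, model, res, mu)
}

warn_near_duplicate_columns <- function(F, tol = 1e-3) {
  m <- ncol(F)
  if (m < 2L) return(invisible(NULL))
  for (j in seq_len(m - 1L)) for (jp in (j + 1L):m) {
    if (all(abs(F[, j] - F[, jp]) <= tol)) {
      warning(sprintf(paste0(
        "columns '%s' and '%s' are near-duplicates; cluster mutations ",
        "before solving to avoid conflicts with the minimum-abundance ",
        "constraint"), colnames(F)[j], colnames(F)[jp]))
      return(invisible(NULL))
    }
  }
  invisible(NULL)
}

# Assemble the MILP in sparse triplet form. Variable layout (1-based):
#   x[e]            e = 1..nE        binary   edge e of G in the clone tree
#   u[i,l]          off_u  + (i-1)m+l continuous  clone proportions
#   up[i,l]         off_up + (i-1)m+l binary     binarization U'
#   f[i,j]          off_f  + (i-1)m+j continuous fitted frequencies UB
#   h[i,k]          off_h  + (i-1)nE1+k continuous x_e * f (non-root edges)
#   c[i,j]          off_c  + (i-1)m+j continuous |F - UB| slacks
#   g[3(p,q)+d]     off_g  + ...      binary     three-gamete indicators
build_nppm_model <- function(F, G, mu) {
  n <- nrow(F); m <- ncol(F)
  E <- G$edges
  nE <- nrow(E)
  e1 <- which(E[, 1L] != 0L)
  E1 <- E[e1, , drop = FALSE]
  nE1 <- nrow(E1)
  pairs <- if (m >= 2L) t(utils::combn(m, 2L)) else matrix(0L, 0L, 2L)
  npair <- nrow(pairs)

  off_u <- nE
  off_up <- off_u + n * m
  off_f <- off_up + n * m
  off_h <- off_f + n * m
  off_c <- off_h + n * nE1
  off_g <- off_c + n * m
  nv <- off_g + 3L * npair

  vx <- function(k) k
  vu <- function(i, l) off_u + (i - 1L) * m + l
  vup <- function(i, l) off_up + (i - 1L) * m + l
  vf <- function(i, j) off_f + (i - 1L) * m + j
  vh <- function(i, k) off_h + (i - 1L) * nE1 + k
  vc <- function(i, j) off_c + (i - 1L) * m + j

  ri <- list(); ci <- list(); vv <- list(); lo <- list(); hi <- list()
  nb <- 0L  # row counter
  blk <- 0L
  push <- function(r, c2, v, l, h) {
    blk <<- blk + 1L
    ri[[blk]] <<- nb + r; ci[[blk]] <<- c2; vv[[blk]] <<- v
    lo[[blk]] <<- l; hi[[blk]] <<- h
    nb <<- nb + length(l)
  }
  iall <- rep(seq_len(n), each = m)          # cell index for (i,l) blocks
  lall <- rep(seq_len(m), times = n)
  t_ul <- vu(iall, lall)                     # u[i,l] columns in layout order
  t_up <- vup(iall, lall)
  t_f <- vf(iall, lall)
  t_c <- vc(iall, lall)
  nm <- n * m

  # (1) exactly one incoming clone-tree edge per mutation vertex
  push(r = E[, 2L], c2 = seq_len(nE), v = rep(1, nE),
       l = rep(1, m), h = rep(1, m))
  # (1b) 2-cycle exclusion (ties between near-identical columns keep both
  #      directions in G; an arborescence can use at most one)
  if (nE1 > 1L) {
    key <- paste(E1[, 1L], E1[, 2L]); rkey <- paste(E1[, 2L], E1[, 1L])
    twin <- match(rkey, key)
    sel2 <- which(!is.na(twin) & seq_len(nE1) < twin)
    if (length(sel2)) {
      n2 <- length(sel2)
      push(r = rep(seq_len(n2), 2L),
           c2 = c(e1[sel2], e1[twin[sel2]]),
           v = rep(1, 2L * n2), l = rep(-Inf, n2), h = rep(1, n2))
    }
  }
  # (2) u <= u'
  push(r = rep(seq_len(nm), 2L), c2 = c(t_ul, t_up),
       v = c(rep(1, nm), rep(-1, nm)), l = rep(-Inf, nm), h = rep(0, nm))
  # (3) u >= mu u'
  push(r = rep(seq_len(nm), 2L), c2 = c(t_ul, t_up),
       v = c(rep(1, nm), rep(-mu, nm)), l = rep(0, nm), h = rep(Inf, nm))
  # (4) row sums of U at most 1 (remainder = wild type)
  push(r = iall, c2 = t_ul, v = rep(1, nm), l = rep(-Inf, n), h = rep(1, n))
  # (5) concordance: up[i,l] >= x_e + up[i,l'] - 1 for e = (l,l') in E1
  if (nE1 > 0L) {
    i3 <- rep(seq_len(n), times = nE1)
    k3 <- rep(seq_len(nE1), each = n)
    r3 <- seq_len(n * nE1)
    push(r = rep(r3, 3L),
         c2 = c(vup(i3, E1[k3, 1L]), e1[k3], vup(i3, E1[k3, 2L])),
         v = c(rep(1, n * nE1), rep(-1, n * nE1), rep(-1, n * nE1)),
         l = rep(-1, n * nE1), h = rep(Inf, n * nE1))
  }
  # (6) fitted frequencies: f[i,j] = u[i,j] + sum_{e=(j,j')} h[i,e]
  hr <- if (nE1 > 0L) {
    i6 <- rep(seq_len(n), times = nE1)
    k6 <- rep(seq_len(nE1), each = n)
    (i6 - 1L) * m + E1[k6, 1L]     # row of (i, tail(e))
  } else integer(0)
  push(r = c(seq_len(nm), seq_len(nm), hr),
       c2 = c(t_f, t_ul, if (nE1 > 0L) vh(i6, k6) else integer(0)),
       v = c(rep(1, nm), rep(-1, nm), rep(-1, length(hr))),
       l = rep(0, nm), h = rep(0, nm))
  # (7) h linearization: h <= f[.,head], h <= x_e, h >= f[.,head] + x_e - 1
  if (nE1 > 0L) {
    i7 <- rep(seq_len(n), times = nE1)
    k7 <- rep(seq_len(nE1), each = n)
    nk <- n * nE1
    hcol <- vh(i7, k7)
    fhead <- vf(i7, E1[k7, 2L])
    xcol <- e1[k7]
    push(r = rep(seq_len(nk), 2L), c2 = c(hcol, fhead),
         v = c(rep(1, nk), rep(-1, nk)), l = rep(-Inf, nk), h = rep(0, nk))
    push(r = rep(seq_len(nk), 2L), c2 = c(hcol, xcol),
         v = c(rep(1, nk), rep(-1, nk)), l = rep(-Inf, nk), h = rep(0, nk))
    push(r = rep(seq_len(nk), 3L), c2 = c(hcol, fhead, xcol),
         v = c(rep(1, nk), rep(-1, nk), rep(-1, nk)),
         l = rep(-1, nk), h = rep(Inf, nk))
    # (7b) valid cut: h[i,e] <= u'[i,tail(e)] (a selected edge with flow
    #      implies the tail clone is present via the concordance chain)
    push(r = rep(seq_len(nk), 2L), c2 = c(hcol, vup(i7, E1[k7, 1L])),
         v = c(rep(1, nk), rep(-1, nk)), l = rep(-Inf, nk), h = rep(0, nk))
  }
  # (8) L1 slacks: c >= F - f and c >= f - F
  fobs <- as.vector(t(F))                    # layout order (i-major, l-minor)
  push(r = rep(seq_len(nm), 2L), c2 = c(t_c, t_f),
       v = c(rep(1, nm), rep(1, nm)), l = fobs, h = rep(Inf, nm))
  push(r = rep(seq_len(nm), 2L), c2 = c(t_c, t_f),
       v = c(rep(1, nm), rep(-1, nm)), l = -fobs, h = rep(Inf, nm))
  # (9) valid cut: a positive fitted frequency forces clone presence
  #     (concordance chains make f[i,j] > 0 imply u'[i,j] = 1)
  push(r = rep(seq_len(nm), 2L), c2 = c(t_f, t_up),
       v = c(rep(1, nm), rep(-1, nm)), l = rep(-Inf, nm), h = rep(0, nm))
  # (10) three-gamete forbidding for U': per clone pair (p,q) binaries
  #      g11, g10, g01 dominate the row patterns; at most two patterns occur
  if (npair > 0L) {
    ip <- rep(seq_len(n), times = npair)
    kp <- rep(seq_len(npair), each = n)
    np3 <- n * npair
    g11 <- off_g + 3L * (kp - 1L) + 1L
    g10 <- g11 + 1L
    g01 <- g11 + 2L
    upp <- vup(ip, pairs[kp, 1L])
    upq <- vup(ip, pairs[kp, 2L])
    push(r = rep(seq_len(np3), 3L), c2 = c(g11, upp, upq),
         v = c(rep(1, np3), rep(-1, np3), rep(-1, np3)),
         l = rep(-1, np3), h = rep(Inf, np3))
    push(r = rep(seq_len(np3), 3L), c2 = c(g10, upp, upq),
         v = c(rep(1, np3), rep(-1, np3), rep(1, np3)),
         l = rep(0, np3), h = rep(Inf, np3))
    push(r = rep(seq_len(np3), 3L), c2 = c(g01, upq, upp),
         v = c(rep(1, np3), rep(-1, np3), rep(1, np3)),
         l = rep(0, np3), h = rep(Inf, np3))
    kg <- seq_len(npair)
    gb <- off_g + 3L * (kg - 1L)
    push(r = rep(kg, 3L), c2 = c(gb + 1L, gb + 2L, gb + 3L),
         v = rep(1, 3L * npair), l = rep(-Inf, npair), h = rep(2, npair))
  }

  obj <- numeric(nv)
  obj[t_c] <- 1
  integrality <- numeric(nv)
  integrality[seq_len(nE)] <- 1
  integrality[t_up] <- 1
  if (npair > 0L) integrality[(off_g + 1L):nv] <- 1

  model <- milp_model(
    n_vars = nv, obj = obj, lb = 0, ub = 1, integrality = integrality,
    a_row = unlist(ri), a_col = unlist(ci), a_val = unlist(vv),
    row_lb = unlist(lo), row_ub = unlist(hi))
  list(model = model, nE = nE, E = E, off_u = off_u, off_up = off_up,
       off_f = off_f, m = m, n = n)
}

extract_solution <- function(F, G, mod, res, mu) {
  n <- mod$n; m <- mod$m
  x <- res$x
  sel <- which(x[seq_len(mod$nE)] > 0.5)
  parent <- integer(m)
  parent[mod$E[sel, 2L]] <- mod$E[sel, 1L]
  S <- clone_tree(parent, labels = as.list(colnames(F)))
  B <- clone_matrix_from_tree(S)
  dimnames(B) <- list(colnames(F), colnames(F))
  U <- matrix(pmin(pmax(x[mod$off_u + seq_len(n * m)], 0), 1),
              n, m, byrow = TRUE, dimnames = dimnames(F))
  Uprime <- matrix(as.integer(x[mod$off_up + seq_len(n * m)] > 0.5),
                   n, m, byrow = TRUE, dimnames = dimnames(F))
  if (mu <= 0) Uprime <- Uprime * binarize(U)  # mu = 0 leaves u' unpinned
  U[Uprime == 0L] <- 0
  Fhat <- U %*% unclass(B)
  T <- lineage_tree_from_binary_matrix(Uprime, cell_ids = rownames(F))
  structure(list(
    U = U, Uprime = Uprime, B = B, S = S, T = T, Fhat = Fhat,
    objective = sum(abs(unclass(F) - Fhat)),
    solver_objective = res$objective, status = res$status,
    mip_gap = res$mip_gap, mu = mu, runtime = res$runtime),
    class = "nppm_solution")
}

#' @export
print.nppm_solution <- function(x, ...) {
  cat(sprintf(
    "NPPM solution: %d cells x %d clones | L1 error %.4f | status %s (%.1fs)\n",
    nrow(x$U), ncol(x$U), x$objective, x$status, x$runtime))
  cat("Clone tree edges (parent -> child):\n")
  print.clone_tree(x$S)
  invisible(x)
}

#' Fitted frequency matrix of a factorization
#'
#' `Fhat = U B`: the modeled heteroplasmic fraction of mutation `j` in cell
#' `i` equals the summed proportions of the clones carrying `j`. Equivalent
#' recursion over the clone tree: `fhat[, j] = U[, j] + sum of fhat over
#' children of j`.
#'
#' @param U mixture matrix (`n x m`).
#' @param B clone matrix (`m x m`).
#' @return `n x m` matrix.
#' @export
compute_fhat <- function(U, B) {
  U <- as.matrix(U); B <- as.matrix(unclass(B))
  if (ncol(U) != nrow(B)) stop("shapes of U and B do not conform")
  U %*% B
}

#' Collapse clustered mutations onto clone-tree vertices
#'
#' After [cluster_mutations()], the solver operates on one column per
#' cluster. This relabels each clone-tree vertex with all member mutations
#' of its cluster, so edge labels carry the full mutation set while the
#' vertex count reflects clusters.
#'
#' @param sol an `"nppm_solution"` (or a [clone_tree()]).
#' @param clusters named list from [cluster_mutations()]; `NULL` leaves the
#'   tree unchanged.
#' @return a [clone_tree()] with (possibly) multi-mutation labels.
#' @export
collapse_clone_tree <- function(sol, clusters = NULL) {
  S <- if (inherits(sol, "nppm_solution")) sol$S else sol
  if (!inherits(S, "clone_tree")) stop("need an nppm_solution or clone_tree")
  if (is.null(clusters)) return(S)
  labels <- lapply(S$labels, function(l) {
    key <- l[1L]
    if (!is.null(clusters[[key]])) clusters[[key]] else l
  })
  clone_tree(S$parent, labels = labels)
}
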