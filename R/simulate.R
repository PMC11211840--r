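# Synthetic-data generator for concordant clone / lineage tree instances.
#
# The stated world: clone trees are growing random networks (uniform random
# attachment); the cell lineage tree grows by uniform random leaf splitting
# to n leaves; clone origins are placed on distinct lineage edges, each
# subtending at least a minimum fraction of cells, concordantly with the
# clone tree; per-cell clone proportions are symmetric-Dirichlet draws
# floored at 0.05; read counts follow a Poisson-coverage beta-binomial.

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a mitochondrial clone tree
#'
#' Growing random network (random recursive tree): clone `k` attaches to a
#' uniformly random vertex among `0..k-1`. Deterministic given `seed`.
#'
#' @param m number of clones/mutations.
#' @param seed integer seed.
#' @return a [clone_tree()].
#' @export
simulate_clone_tree <- function(m, seed = 1L) {
  stopifnot(m >= 1L)
  with_seed(seed, {
    parent <- integer(m)
    for (k in seq_len(m)) parent[k] <- sample.int(k, 1L) - 1L
    clone_tree(parent)
  })
}

# grow a rooted binary lineage tree by uniform random leaf splitting;
# returns parent pointers over all vertices (1 = founder root, parent 0),
# plus children lists and the leaf vertex of each cell
grow_lineage_topology <- function(n) {
  parent <- c(0L, 1L)         # founder 1 -> first cell lineage 2
  children <- list(2L, integer(0))
  leaves <- 2L
  while (length(leaves) < n) {
    pick <- leaves[sample.int(length(leaves), 1L)]
    a <- length(parent) + 1L; b <- a + 1L
    parent <- c(parent, pick, pick)
    children[[pick]] <- c(a, b)
    children[[a]] <- integer(0); children[[b]] <- integer(0)
    leaves <- c(setdiff(leaves, pick), a, b)
  }
  list(parent = parent, children = children, leaves = sort(leaves))
}

#' Simulate a concordant cell lineage tree and mixture matrix
#'
#' The lineage tree grows by uniform random leaf splitting until it has `n`
#' leaves (cells). Clone origins are then placed on distinct lineage edges,
#' in clone-tree order, each origin drawn uniformly among the edges that
#' (i) lie at or below the parent clone's origin edge, (ii) subtend at
#' least `ceil(min_clade_frac * n)` cells, and (iii) can still host the
#' clone's entire subtree on nested distinct edges; the assignment is
#' resampled when it dead-ends. Every cell's clone proportions are a
#' symmetric Dirichlet over its present clones plus wild type, floored at
#' 0.05 so the minimum-abundance constraint of the solver is satisfiable by
#' the truth.
#'
#' @param S a [clone_tree()].
#' @param n number of cells.
#' @param seed integer seed.
#' @param dirichlet_alpha symmetric Dirichlet concentration (default 2).
#' @param min_clade_frac minimum fraction of cells below a clone origin
#'   (default 0.02; at least one cell).
#' @return list with `T` (a `"lineage_tree"`) and `U` (mixture matrix with
#'   positive entries at least 0.05 and row sums at most 1).
#' @export
simulate_lineage_and_mixtures <- function(S, n, seed = 1L,
                                          dirichlet_alpha = 2,
                                          min_clade_frac = 0.02) {
  if (!inherits(S, "clone_tree")) S <- clone_tree(S)
  m <- S$m
  stopifnot(n >= 1L)
  with_seed(seed, {
    minleaf <- max(1L, ceiling(min_clade_frac * n))
    need <- rep(1L, m)                     # clones at or below each clone
    for (j in rev(seq_len(m))) {
      p <- S$parent[j]
      if (p != 0L) need[p] <- need[p] + need[j]
    }
    placed <- NULL
    for (attempt_T in seq_len(50L)) {
      topo <- grow_lineage_topology(n)
      nv <- length(topo$parent)
      nleaf <- integer(nv)
      ord <- order(depth_from_parent(topo$parent))     # shallow to deep
      for (v in rev(ord)) {
        ch <- topo$children[[v]]
        nleaf[v] <- if (length(ch) == 0L) 1L else sum(nleaf[ch])
      }
      # nested-chain capacity of the edge into v: longest descending chain
      # of distinct edges below (and including) it with >= minleaf cells
      cap <- integer(nv)
      for (v in rev(ord)) {
        if (nleaf[v] < minleaf) { cap[v] <- 0L; next }
        ch <- topo$children[[v]]
        cap[v] <- 1L + if (length(ch) == 0L) 0L else max(cap[ch])
      }
      for (attempt_O in seq_len(200L)) {
        origin <- rep(NA_integer_, m)
        used <- logical(nv)
        ok <- TRUE
        for (j in seq_len(m)) {
          p <- S$parent[j]
          pool <- if (p == 0L) which(cap >= need[j] & !used)
                  else {
                    sub <- subtree_vertices(topo$children, origin[p])
                    sub[cap[sub] >= need[j] & !used[sub]]
                  }
          if (length(pool) == 0L) { ok <- FALSE; break }
          origin[j] <- pool[sample.int(length(pool), 1L)]
          used[origin[j]] <- TRUE
        }
        if (ok) { placed <- list(topo = topo, origin = origin,
                                 nleaf = nleaf); break }
      }
      if (!is.null(placed)) break
    }
    if (is.null(placed))
      stop(sprintf(paste0("could not place %d clones on a lineage tree of ",
                          "%d cells (min_clade_frac = %g); increase n or ",
                          "lower min_clade_frac"), m, n, min_clade_frac))
    build_ground_lineage(S, placed, n, dirichlet_alpha)
  })
}

depth_from_parent <- function(parent) {
  nv <- length(parent)
  d <- integer(nv)
  for (v in seq_len(nv)) {
    u <- parent[v]; k <- 0L
    while (u != 0L) { k <- k + 1L; u <- parent[u] }
    d[v] <- k
  }
  d
}

subtree_vertices <- function(children, v) {
  out <- integer(0); stack <- v
  while (length(stack)) {
    w <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, w)
    stack <- c(stack, children[[w]])
  }
  sort(out)
}

build_ground_lineage <- function(S, placed, n, dirichlet_alpha) {
  topo <- placed$topo; origin <- placed$origin
  m <- S$m
  nv <- length(topo$parent)
  is_leaf <- vapply(topo$children, length, 1L) == 0L
  # splice a unary vertex above any leaf that hosts a clone origin, so that
  # sequenced cells remain strict leaves
  for (j in seq_len(m)) {
    v <- origin[j]
    if (is_leaf[v]) {
      w <- length(topo$parent) + 1L
      topo$parent <- c(topo$parent, topo$parent[v])
      topo$children[[topo$parent[v]]] <-
        replace(topo$children[[topo$parent[v]]],
                topo$children[[topo$parent[v]]] == v, w)
      topo$children[[w]] <- v
      topo$parent[v] <- w
      is_leaf <- c(is_leaf, FALSE)
      origin[origin == v & !is.na(origin)] <- w
    }
  }
  nv <- length(topo$parent)
  internal <- which(!is_leaf)
  leaves <- which(is_leaf)
  imap <- integer(nv)
  imap[internal] <- order(order(depth_from_parent(topo$parent)[internal],
                                internal))  # stable renumber, root first
  parent_int <- integer(length(internal))
  for (v in internal) {
    p <- topo$parent[v]
    parent_int[imap[v]] <- if (p == 0L) 0L else imap[p]
  }
  cell_ids <- paste0("cell", seq_len(n))
  leaf_parent <- imap[topo$parent[leaves]]
  T <- structure(list(parent = parent_int, origin = imap[origin],
                      leaf_parent = leaf_parent, cell_ids = cell_ids, m = m),
                 class = "lineage_tree")
  # clones present in a cell = origins on the leaf's root path
  U <- matrix(0, n, m, dimnames = list(cell_ids, paste0("mut", seq_len(m))))
  floor_p <- 0.05
  for (i in seq_along(leaves)) {
    path <- integer(0)
    v <- topo$parent[leaves[i]]
    while (v != 0L) { path <- c(path, v); v <- topo$parent[v] }
    present <- which(!is.na(origin) & origin %in% path)
    k <- length(present)
    if (k == 0L) next
    if (floor_p * (k + 1) >= 1)
      stop("too many clones per cell for the 0.05 proportion floor")
    w <- stats::rgamma(k + 1L, shape = dirichlet_alpha)
    w <- w / sum(w)
    U[i, present] <- floor_p + w[-1L] * (1 - floor_p * (k + 1))
  }
  list(T = T, U = U)
}

#' Simulate beta-binomial read counts for a frequency matrix
#'
#' Per cell and mutation: total reads are Poisson(`coverage_mean`), floored
#' at 1; the variant count is beta-binomial with mean `f` and precision `s`
#' (p drawn from Beta(`f*s`, `(1-f)*s`)). Frequencies of exactly 0 or 1
#' give deterministic counts 0 or total.
#'
#' @param F frequency matrix.
#' @param coverage_mean mean reads per site per cell (default 100).
#' @param s beta precision; larger is less overdispersed (default 50).
#' @param seed integer seed.
#' @return list with integer matrices `variant` and `total`.
#' @export
simulate_reads <- function(F, coverage_mean = 100, s = 50, seed = 1L) {
  stopifnot(coverage_mean > 0, s > 0)
  F <- as_freq(F)
  n <- nrow(F); m <- ncol(F)
  with_seed(seed, {
    total <- matrix(pmax(stats::rpois(n * m, coverage_mean), 1L), n, m,
                    dimnames = dimnames(F))
    p <- matrix(0, n, m)
    mid <- unclass(F) > 0 & unclass(F) < 1
    p[mid] <- stats::rbeta(sum(mid), unclass(F)[mid] * s,
                           (1 - unclass(F)[mid]) * s)
    p[unclass(F) >= 1] <- 1
    variant <- matrix(stats::rbinom(n * m, as.vector(total), as.vector(p)),
                      n, m, dimnames = dimnames(F))
    list(variant = variant, total = total)
  })
}

#' Simulate a complete concordant ground-truth instance
#'
#' Chains [simulate_clone_tree()], [simulate_lineage_and_mixtures()] and
#' [simulate_reads()] with sub-seeds derived from `seed`, optionally
#' applying random mutation loss ([apply_clone_loss()]).
#'
#' @param n_cells,m_mutations instance size.
#' @param coverage_mean,s read-count model parameters (defaults 100 and 50).
#' @param dirichlet_alpha proportion concentration (default 2).
#' @param min_clade_frac minimum clone support fraction (default 0.02).
#' @param p_loss per-entry mutation-loss probability (default 0).
#' @param seed integer master seed.
#' @return object of class `"nppm_ground_truth"`: `S`, `T`, `U`, `Uprime`,
#'   `B`, `F` (true frequencies `U B`), `M` (true mutation matrix),
#'   `variant`, `total`, `Fobs` (`variant/total`), and `config`.
#' @export
simulate_instance <- function(n_cells, m_mutations, coverage_mean = 100,
                              s = 50, dirichlet_alpha = 2,
                              min_clade_frac = 0.02, p_loss = 0, seed = 1L) {
  seed <- as.integer(seed)
  S <- simulate_clone_tree(m_mutations, seed = seed)
  S$labels <- as.list(paste0("mut", seq_len(m_mutations)))
  lt <- simulate_lineage_and_mixtures(S, n_cells, seed = seed + 1000L,
                                      dirichlet_alpha = dirichlet_alpha,
                                      min_clade_frac = min_clade_frac)
  B <- clone_matrix_from_tree(S)
  F <- lt$U %*% unclass(B)
  colnames(F) <- paste0("mut", seq_len(m_mutations))
  gt <- structure(list(
    S = S, T = lt$T, U = lt$U, Uprime = binarize(lt$U), B = B,
    F = F, M = binarize(F), variant = NULL, total = NULL, Fobs = NULL,
    config = list(n_cells = n_cells, m_mutations = m_mutations,
                  coverage_mean = coverage_mean, s = s,
                  dirichlet_alpha = dirichlet_alpha,
                  min_clade_frac = min_clade_frac, p_loss = p_loss,
                  seed = seed)),
    class = "nppm_ground_truth")
  if (p_loss > 0) gt <- apply_clone_loss(gt, p_loss, seed = seed + 2000L)
  reads <- simulate_reads(gt$F, coverage_mean = coverage_mean, s = s,
                          seed = seed + 3000L)
  gt$variant <- reads$variant
  gt$total <- reads$total
  gt$Fobs <- frequency_matrix(reads$variant / reads$total,
                              cell_ids = rownames(gt$F),
                              mutation_ids = colnames(gt$F))
  gt
}

#' @export
print.nppm_ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d cells x %d mutations (seed %d%s)\n",
              nrow(x$F), ncol(x$F), x$config$seed,
              if (x$config$p_loss > 0)
                sprintf(", p_loss %g", x$config$p_loss) else ""))
  invisible(x)
}

#' Perturb a ground truth by random mutation loss
#'
#' Violates the no-extinction model assumption: each positive frequency
#' entry is set to zero independently with probability `p_loss` (the
#' mutation is lost in that cell); the matching binarized-mixture entry is
#' zeroed too, and the true mutation matrix is recomputed. Read counts, if
#' present, must be regenerated from the perturbed frequencies (as
#' [simulate_instance()] does).
#'
#' @param gt an `"nppm_ground_truth"`.
#' @param p_loss loss probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the perturbed ground truth.
#' @export
apply_clone_loss <- function(gt, p_loss, seed = 1L) {
  stopifnot(inherits(gt, "nppm_ground_truth"), p_loss >= 0, p_loss <= 1)
  if (p_loss == 0) return(gt)
  with_seed(seed, {
    pos <- which(gt$F > 0)
    lost <- pos[stats::runif(length(pos)) < p_loss]
    gt$F[lost] <- 0
    # a clone that loses its defining mutation in a cell is no longer that
    # clone there: zero the matching mixture-support entries
    gt$U[lost] <- 0
    gt$Uprime <- binarize(gt$U)
    gt$M <- binarize(gt$F)
    gt$config$p_loss <- p_loss
    gt
  })
}
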