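# Shared helpers: independent oracles and small random generators.

# Independent three-gamete check: explicit row loops, no linear algebra.
pp_oracle <- function(M) {
  M <- as.matrix(M)
  m <- ncol(M)
  if (m < 2L) return(TRUE)
  for (p in seq_len(m - 1L)) for (q in (p + 1L):m) {
    seen <- c(g10 = FALSE, g01 = FALSE, g11 = FALSE)
    for (i in seq_len(nrow(M))) {
      a <- M[i, p]; b <- M[i, q]
      if (a == 1 && b == 0) seen["g10"] <- TRUE
      if (a == 0 && b == 1) seen["g01"] <- TRUE
      if (a == 1 && b == 1) seen["g11"] <- TRUE
    }
    if (all(seen)) return(FALSE)
  }
  TRUE
}

# random arborescence parent vector on m clones (uniform attachment)
random_parent <- function(m) {
  vapply(seq_len(m), function(k) sample.int(k, 1L) - 1L, 1L)
}

# random ancestor-closed binary row for a clone tree (downward-closed set)
random_closed_row <- function(S) {
  m <- S$m
  row <- integer(m)
  for (j in seq_len(m)) {
    p <- S$parent[j]
    if (p == 0L || row[p] == 1L) row[j] <- rbinom(1L, 1L, 0.6)
  }
  row
}

# deterministic small frequency matrix with exact factorization
make_feasible_freq <- function(n, m, seed) {
  gt <- simulate_instance(n, m, seed = seed)
  gt
}

solver_time <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  val <- force(expr)
  list(value = val, elapsed = proc.time()[["elapsed"]] - t0)
}
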