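# Thin deterministic bridge to the HiGHS mixed-integer solver.
#
# The environment provides no MILP solver as an R library, but the bundled
# scientific Python (same conda env, `python` on PATH) ships scipy whose
# `optimize.milp` wraps HiGHS. Models are assembled here as sparse triplets,
# exchanged through a temp directory (JSON header + one float64 binary
# block), and solved by inst/python/highs_solve.py. Single-threaded HiGHS
# with a fixed variable order makes results reproducible.

MILP_INF <- 1e30

#' Construct a MILP model in triplet form
#'
#' Internal-but-exported building block for the exact solvers in this
#' package. Rows are two-sided ranges `row_lb <= a'x <= row_ub`; use
#' `-Inf`/`Inf` for one-sided rows.
#'
#' @param n_vars number of variables.
#' @param obj objective coefficients (minimized).
#' @param lb,ub variable bounds (recycled).
#' @param integrality 0 = continuous, 1 = integer (recycled).
#' @param a_row,a_col 1-based triplet indices.
#' @param a_val triplet values.
#' @param row_lb,row_ub row bounds.
#' @return list of class `"milp_model"`.
#' @keywords internal
#' @export
milp_model <- function(n_vars, obj, lb = 0, ub = 1, integrality = 0,
                       a_row, a_col, a_val, row_lb, row_ub) {
  stopifnot(length(a_row) == length(a_col), length(a_col) == length(a_val),
            length(row_lb) == length(row_ub))
  structure(list(
    n_vars = as.integer(n_vars),
    obj = rep_len(as.double(obj), n_vars),
    lb = rep_len(as.double(lb), n_vars),
    ub = rep_len(as.double(ub), n_vars),
    integrality = rep_len(as.double(integrality), n_vars),
    a_row = as.double(a_row), a_col = as.double(a_col),
    a_val = as.double(a_val),
    row_lb = as.double(row_lb), row_ub = as.double(row_ub),
    n_rows = length(row_lb)
  ), class = "milp_model")
}

python_binary <- function() {
  p <- Sys.getenv("NPPM_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no 'python' found on PATH; set NPPM_PYTHON")
  p
}

solver_script <- function() {
  s <- system.file("python", "highs_solve.py", package = "nppm")
  if (!nzchar(s)) stop("bundled solver script not found; is the package installed?")
  s
}

#' Solve a MILP model with the HiGHS backend
#'
#' @param model a [milp_model()].
#' @param time_limit wall-clock limit in seconds (`NULL` = none).
#' @param mip_rel_gap relative optimality gap (default 0: prove optimality).
#' @param verbose print solver call information.
#' @return list with `status` (`"optimal"`, `"limit_reached"`,
#'   `"infeasible"`, ...), `objective`, `x` (variable values or `NULL`),
#'   `mip_gap`, `runtime` (seconds).
#' @keywords internal
#' @export
milp_solve <- function(model, time_limit = NULL, mip_rel_gap = 0,
                       verbose = FALSE) {
  stopifnot(inherits(model, "milp_model"))
  dir <- tempfile("nppm_milp_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  blocks <- list(obj = model$obj, lb = model$lb, ub = model$ub,
                 integrality = model$integrality,
                 a_row = model$a_row - 1, a_col = model$a_col - 1,
                 a_val = model$a_val,
                 row_lb = model$row_lb, row_ub = model$row_ub)
  meta <- list(n_vars = model$n_vars, n_rows = model$n_rows,
               block_names = names(blocks),
               block_lengths = vapply(blocks, length, 1L),
               time_limit = time_limit, mip_rel_gap = mip_rel_gap)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(dir, "arrays.bin"), "wb")
  for (b in blocks) {
    v <- as.double(b)
    v[v == Inf] <- MILP_INF
    v[v == -Inf] <- -MILP_INF
    writeBin(v, con, size = 8L, endian = "little")
  }
  close(con)
  t0 <- proc.time()[["elapsed"]]
  out <- system2(python_binary(), c(shQuote(solver_script()), shQuote(dir)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  runtime <- proc.time()[["elapsed"]] - t0
  if (verbose && length(out)) message(paste(out, collapse = "\n"))
  sol_path <- file.path(dir, "solution.json")
  if (!is.null(status) && status != 0L || !file.exists(sol_path))
    stop("MILP backend failed:\n", paste(out, collapse = "\n"))
  sol <- jsonlite::read_json(sol_path, simplifyVector = TRUE)
  x <- NULL
  if (isTRUE(sol$has_solution)) {
    xcon <- file(file.path(dir, "x.bin"), "rb")
    x <- readBin(xcon, "double", n = model$n_vars, size = 8L,
                 endian = "little")
    close(xcon)
  }
  list(status = sol$status, status_code = sol$status_code,
       objective = sol$objective, x = x, mip_gap = sol$mip_gap,
       message = sol$message, runtime = runtime)
}
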