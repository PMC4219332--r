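# LP/MILP/QP back end: problems are serialized to JSON and solved in a
# single python process per batch (SciPy/HiGHS).  No R solver library is
# assumed; python + scipy are the only external requirements.

.fluxmod_env <- new.env(parent = emptyenv())

#' Locate the python interpreter used for optimization
#'
#' The interpreter is resolved once per session from, in order, the option
#' `fluxmod.python`, the environment variable `FLUXMOD_PYTHON`, then
#' `python` / `python3` on the PATH. It must provide `numpy` and `scipy`
#' (>= 1.9, for `scipy.optimize.milp`).
#'
#' @return Path to the python executable.
#' @export
fluxmod_python <- function() {
  if (!is.null(.fluxmod_env$python)) return(.fluxmod_env$python)
  cand <- c(getOption("fluxmod.python", ""),
            Sys.getenv("FLUXMOD_PYTHON", ""),
            Sys.which("python"), Sys.which("python3"))
  cand <- cand[nzchar(cand)]
  if (length(cand) == 0L)
    stop("no python interpreter found; set options(fluxmod.python=...)")
  .fluxmod_env$python <- cand[[1L]]
  .fluxmod_env$python
}

bridge_script <- function() {
  p <- system.file("python", "milp_bridge.py", package = "fluxmod")
  if (!nzchar(p)) stop("milp_bridge.py not found in installed package")
  p
}

INF_SENTINEL <- 1e30

finitize <- function(x) {
  x[x == Inf] <- INF_SENTINEL
  x[x == -Inf] <- -INF_SENTINEL
  x
}

## --- incremental model builder -------------------------------------------

new_mip <- function() {
  m <- new.env(parent = emptyenv())
  m$var_name <- character()
  m$var_lb <- numeric()
  m$var_ub <- numeric()
  m$var_obj <- numeric()
  m$var_int <- logical()
  m$row_i <- list()   # per-row variable indices
  m$row_x <- list()   # per-row coefficients
  m$row_lb <- numeric()
  m$row_ub <- numeric()
  m$row_name <- character()
  class(m) <- "mip_model"
  m
}

add_var <- function(m, name, lb = 0, ub = Inf, obj = 0, integer = FALSE) {
  k <- length(m$var_name) + 1L
  m$var_name[k] <- name
  m$var_lb[k] <- lb
  m$var_ub[k] <- ub
  m$var_obj[k] <- obj
  m$var_int[k] <- integer
  k
}

add_vars <- function(m, names, lb = 0, ub = Inf, obj = 0, integer = FALSE) {
  vapply(seq_along(names), function(j)
    add_var(m, names[[j]],
            lb = rep_len(lb, length(names))[j],
            ub = rep_len(ub, length(names))[j],
            obj = rep_len(obj, length(names))[j],
            integer = rep_len(integer, length(names))[j]),
    integer(1L))
}

add_row <- function(m, idx, coef, lb = -Inf, ub = Inf, name = "") {
  keep <- coef != 0
  k <- length(m$row_lb) + 1L
  m$row_i[[k]] <- as.integer(idx[keep])
  m$row_x[[k]] <- as.numeric(coef[keep])
  m$row_lb[k] <- lb
  m$row_ub[k] <- ub
  m$row_name[k] <- name
  k
}

n_rows <- function(m) length(m$row_lb)
n_vars <- function(m) length(m$var_name)

var_index <- function(m, name) {
  idx <- match(name, m$var_name)
  if (anyNA(idx)) stop("unknown variable: ", paste(name[is.na(idx)], collapse = ", "))
  idx
}

mip_problem <- function(m, options = list()) {
  nr <- n_rows(m)
  lens <- lengths(m$row_i)
  list(type = "milp",
       c = m$var_obj,
       A = list(i = rep.int(seq_len(nr) - 1L, lens),
                j = unlist(m$row_i, use.names = FALSE) - 1L,
                x = unlist(m$row_x, use.names = FALSE),
                nrow = nr, ncol = n_vars(m)),
       rlb = finitize(m$row_lb),
       rub = finitize(m$row_ub),
       lb = finitize(m$var_lb),
       ub = finitize(m$var_ub),
       integrality = as.integer(m$var_int),
       options = options)
}

## --- direct problem constructors -----------------------------------------

# Dense-matrix LP/MILP in row-bound form: rlb <= A x <= rub, lb <= x <= ub.
lp_problem <- function(c, A, rlb, rub, lb, ub, integrality = NULL,
                       options = list()) {
  A <- as.matrix(A)
  nz <- which(A != 0, arr.ind = TRUE)
  list(type = "milp", c = as.numeric(c),
       A = list(i = as.integer(nz[, 1L] - 1L), j = as.integer(nz[, 2L] - 1L),
                x = as.numeric(A[nz]), nrow = nrow(A), ncol = ncol(A)),
       rlb = finitize(as.numeric(rlb)), rub = finitize(as.numeric(rub)),
       lb = finitize(as.numeric(lb)), ub = finitize(as.numeric(ub)),
       integrality = if (is.null(integrality)) integer(ncol(A)) else as.integer(integrality),
       options = options)
}

# Box+row constrained least squares min ||x - target||^2 (L2-MOMA).
qp_problem <- function(target, A, rlb, rub, lb, ub) {
  A <- as.matrix(A)
  nz <- which(A != 0, arr.ind = TRUE)
  list(type = "qp", target = as.numeric(target),
       A = list(i = as.integer(nz[, 1L] - 1L), j = as.integer(nz[, 2L] - 1L),
                x = as.numeric(A[nz]), nrow = nrow(A), ncol = ncol(A)),
       rlb = finitize(as.numeric(rlb)), rub = finitize(as.numeric(rub)),
       lb = finitize(as.numeric(lb)), ub = finitize(as.numeric(ub)))
}

## --- bridge ----------------------------------------------------------------

# Solve a list of problems in one python invocation.  Returns a list of
# results: list(status, objective, x, message).
solve_programs <- function(problems) {
  stopifnot(is.list(problems))
  if (length(problems) == 0L) return(list())
  infile <- tempfile("fluxmod_in_", fileext = ".json")
  outfile <- tempfile("fluxmod_out_", fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(list(problems = problems), infile,
                       auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(fluxmod_python(), c(bridge_script(), infile, outfile),
                    stdout = NULL, stderr = "")
  if (!identical(status, 0L) || !file.exists(outfile))
    stop("optimization bridge failed (exit status ", status, ")")
  out <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)
  lapply(out$results, function(r) {
    list(status = r$status %||% "error",
         objective = if (!is.null(r$objective)) as.numeric(r$objective) else NA_real_,
         x = if (!is.null(r$x)) as.numeric(unlist(r$x)) else NULL,
         message = r$message %||% "")
  })
}

solve_program <- function(problem) solve_programs(list(problem))[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a
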