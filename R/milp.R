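#' Create an empty MILP model
#'
#' A minimal, backend-agnostic container for mixed-integer linear programs:
#' named variables with a domain (binary, non-negative integer, continuous)
#' and bounds, named linear constraints, and a linear objective that is
#' minimized. All formulations in this package are declared against this
#' container so they stay independent of the solver.
#'
#' @return A `milp_problem` (environment-backed builder).
#' @export
milp_problem <- function() {
  p <- new.env(parent = emptyenv())
  p$var_name <- character(0)
  p$var_type <- character(0)   # "binary", "integer", "continuous"
  p$var_lb <- numeric(0)
  p$var_ub <- numeric(0)
  p$obj <- numeric(0)
  p$cons <- list()             # list of list(coefs=named num, sense, rhs)
  p$con_name <- character(0)
  class(p) <- "milp_problem"
  p
}

#' Add variables to a MILP model
#'
#' @param p A `milp_problem`.
#' @param names Character vector of new, unique variable names.
#' @param type One of `"binary"`, `"integer"` (non-negative by default),
#'   `"continuous"`; recycled.
#' @param lb,ub Bounds, recycled (`binary` forces 0/1).
#' @param obj Objective coefficients, recycled.
#' @return The model, invisibly (modified in place).
#' @export
milp_add_variables <- function(p, names, type = "integer", lb = 0, ub = Inf,
                               obj = 0) {
  stopifnot(inherits(p, "milp_problem"), !any(names %in% p$var_name),
            !anyDuplicated(names))
  n <- length(names)
  type <- rep_len(type, n)
  stopifnot(all(type %in% c("binary", "integer", "continuous")))
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  lb[type == "binary"] <- 0
  ub[type == "binary"] <- 1
  p$var_name <- c(p$var_name, names)
  p$var_type <- c(p$var_type, type)
  p$var_lb <- c(p$var_lb, lb)
  p$var_ub <- c(p$var_ub, ub)
  p$obj <- c(p$obj, rep_len(obj, n))
  invisible(p)
}

#' Add a linear constraint to a MILP model
#'
#' @param p A `milp_problem`.
#' @param coefs Named numeric vector of coefficients over declared variables.
#' @param sense One of `"<="`, `">="`, `"=="`.
#' @param rhs Right-hand side scalar.
#' @param name Optional constraint name.
#' @return The model, invisibly (modified in place).
#' @export
milp_add_constraint <- function(p, coefs, sense, rhs, name = NULL) {
  stopifnot(inherits(p, "milp_problem"), sense %in% c("<=", ">=", "=="))
  if (!all(names(coefs) %in% p$var_name)) {
    stop("constraint references undeclared variables: ",
         paste(setdiff(names(coefs), p$var_name), collapse = ", "))
  }
  k <- length(p$cons) + 1L
  p$cons[[k]] <- list(coefs = coefs, sense = sense, rhs = rhs)
  p$con_name <- c(p$con_name, if (is.null(name)) sprintf("c%d", k) else name)
  invisible(p)
}

#' Set objective coefficients
#' @param p A `milp_problem`.
#' @param coefs Named numeric vector (variables not named keep their current
#'   coefficient).
#' @return The model, invisibly.
#' @export
milp_set_objective <- function(p, coefs) {
  ix <- match(names(coefs), p$var_name)
  stopifnot(!anyNA(ix))
  p$obj[ix] <- unname(coefs)
  invisible(p)
}

#' @export
print.milp_problem <- function(x, ...) {
  cat(sprintf("milp_problem: %d variables (%d integer/binary), %d constraints\n",
              length(x$var_name), sum(x$var_type != "continuous"),
              length(x$cons)))
  invisible(x)
}

# locate the python interpreter used for the HiGHS backend
gted_python <- function() {
  py <- getOption("gted.python", Sys.getenv("GTED_PYTHON", ""))
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the HiGHS backend; ",
                        "set options(gted.python=...)")
  py
}

#' Solve a MILP model
#'
#' Solves the model with the HiGHS solver (via SciPy's `milp` interface,
#' called through the system Python), single-threaded and therefore
#' deterministic for a fixed model. With `relax = TRUE` all integrality
#' requirements are dropped and the continuous relaxation is solved, whose
#' optimum is a lower bound on the integer optimum.
#'
#' @param p A `milp_problem`.
#' @param relax Logical; solve the LP relaxation.
#' @param time_limit Optional wall-clock limit in seconds.
#' @param seed Integer passed to the backend where supported (HiGHS is
#'   deterministic; the seed is recorded in the statistics).
#' @return A `milp_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`, `"limit-reached"`), `objective`,
#'   `assignment` (named vector), and `stats`. Integer variables in an
#'   optimal assignment are rounded after an integrality check (tolerance
#'   1e-6).
#' @export
solve_milp <- function(p, relax = FALSE, time_limit = NULL, seed = NULL) {
  stopifnot(inherits(p, "milp_problem"))
  nv <- length(p$var_name)
  stopifnot(nv > 0)
  vix <- seq_len(nv)
  names(vix) <- p$var_name
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  nc <- length(p$cons)
  sense <- character(nc); rhs <- numeric(nc)
  for (k in seq_len(nc)) {
    cn <- p$cons[[k]]
    j <- unname(vix[names(cn$coefs)])
    rows <- c(rows, rep.int(k, length(j)))
    cols <- c(cols, j)
    vals <- c(vals, unname(cn$coefs))
    sense[k] <- cn$sense
    rhs[k] <- cn$rhs
  }
  payload <- list(
    n = nv,
    obj = p$obj,
    vtype = p$var_type,
    lb = pmax(p$var_lb, -1e30),   # +-1e30 stand in for +-Inf in JSON
    ub = pmin(p$var_ub, 1e30),
    rows = rows, cols = cols, vals = vals,
    sense = sense, rhs = rhs,
    relax = isTRUE(relax),
    time_limit = if (is.null(time_limit)) -1 else as.numeric(time_limit)
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "milp_solve.py", package = "gted")
  if (!nzchar(script)) stop("bundled solver script not found")
  t0 <- proc.time()[["elapsed"]]
  rc <- system2(gted_python(), args = c(shQuote(script), shQuote(fin),
                                        shQuote(fout)),
                stdout = FALSE, stderr = "")
  wall <- proc.time()[["elapsed"]] - t0
  if (rc != 0 || !file.exists(fout)) {
    stop("MILP backend failed (exit code ", rc, ")")
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  status <- res$status
  assignment <- NULL
  objective <- NA_real_
  if (status == "optimal") {
    x <- as.numeric(res$x)
    intv <- p$var_type != "continuous" & !relax
    if (any(intv) && max(abs(x[intv] - round(x[intv]))) > 1e-6) {
      stop("solver returned non-integral values for integer variables")
    }
    x[intv] <- round(x[intv])
    assignment <- setNames(x, p$var_name)
    objective <- sum(p$obj * x)
  }
  structure(list(status = status, objective = objective,
                 assignment = assignment,
                 stats = list(wall = wall, seed = seed,
                              backend = "highs/scipy",
                              message = res$message)),
            class = "milp_solution")
}

#' @export
print.milp_solution <- function(x, ...) {
  cat(sprintf("milp_solution: status %s, objective %s\n", x$status,
              format(x$objective)))
  invisible(x)
}
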