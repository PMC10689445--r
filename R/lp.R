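#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A %*% x = b` and
#' `lb <= x <= ub`, using the package's dense bounded-variable two-phase
#' primal simplex.  This is the computational core behind [solve_fba()] and
#' [solve_pfba()]; it is exported so that the linear programs can be
#' formulated and checked independently of the metabolic-model layer.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix, `m x n`.
#' @param b right-hand side, length `m`.
#' @param lb,ub variable bounds, length `n`; `lb` must be finite, `ub` may
#'   be `Inf`.
#' @param maximize logical; minimize when `FALSE`.
#' @param maxit simplex iteration cap per phase.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"maxit"`), `objective` and the solution vector `x`
#'   (the latter two only when optimal).
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, maxit = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n,
            length(ub) == n)
  if (any(!is.finite(lb)))
    stop("lp_solve requires finite lower bounds")
  if (any(lb > ub))
    stop("infeasible bounds: lb > ub")

  # shift to x' = x - lb >= 0
  b2 <- b - as.numeric(A %*% lb)
  u2 <- ub - lb
  c2 <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  res <- .simplex_box(A, b2, c2, u2, maxit = as.integer(maxit))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "maxit")
  if (status != "optimal")
    return(list(status = status, objective = NA_real_, x = NULL))

  x <- res$x + lb
  objective <- sum(obj * x)
  # sanity: solution must satisfy the constraints it claims to
  resid <- max(abs(as.numeric(A %*% x) - b))
  if (resid > 1e-6 || any(x < lb - 1e-6) || any(x > ub + 1e-6))
    return(list(status = "numerical", objective = NA_real_, x = NULL))
  list(status = "optimal", objective = objective, x = x)
}
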