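# Thin interface over the bounded-variable simplex kernel in src/simplex.cpp.

# Largest bound magnitude handed to the kernel; models use |bound| <= 1000,
# auxiliary slack columns use this cap.
.LP_BIG <- 1e6

#' Solve a bounded linear program
#'
#' Minimises or maximises `obj %*% x` subject to `A %*% x == b` and
#' `lb <= x <= ub`. This is the numerical kernel behind every flux solve in
#' the package; it is exposed for testing and for the enumeration oracle's
#' cross-checks. Infinite bounds are clamped to +/- 1e6.
#'
#' @param obj numeric objective vector.
#' @param A constraint matrix (dense or `Matrix` sparse), may have 0 rows.
#' @param b right-hand side, length `nrow(A)`.
#' @param lb,ub variable bounds, recycled to `length(obj)`.
#' @param maximize if `TRUE` (default) maximise the objective.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"numerical"`), `objective` and the primal vector `x`.
#' @keywords internal
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A))
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  lb <- pmax(lb, -.LP_BIG)
  ub <- pmin(ub, .LP_BIG)
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)
  res <- .simplex_solve(A, as.numeric(b), cvec, lb, ub)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible", "numerical")
  objective <- if (status == "optimal") {
    if (maximize) -res$objective else res$objective
  } else NA_real_
  x <- if (status == "optimal") as.numeric(res$x) else NULL
  list(status = status, objective = objective, x = x)
}
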