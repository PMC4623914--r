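# Exhaustive vertex enumeration for small flux polytopes.
#
# A vertex of {A v = b, lb <= v <= ub} is a basic solution: choose r =
# rank(A) basis columns, put every nonbasic variable on one of its bounds,
# and solve the r x r system. Enumerating all basis subsets and all bound
# assignments visits every vertex, so maxima of linear objectives over the
# polytope (FBA) and per-coordinate ranges under an objective constraint
# (FVA) can be computed by brute force, completely independently of the
# simplex kernel. Tractable for networks up to ~16 reactions with a handful
# of degrees of freedom; used as the test oracle and to fill toy-model
# manifests.

#' Enumerate the vertices of a bounded flux polytope
#'
#' @param A equality-constraint matrix.
#' @param b right-hand side.
#' @param lb,ub finite variable bounds.
#' @param tol feasibility tolerance.
#' @param max_bases safety cap on `choose(n, rank)`.
#' @return matrix with one row per vertex (possibly 0 rows when infeasible).
#' @export
enumerate_vertices <- function(A, b, lb, ub, tol = 1e-9, max_bases = 2e5) {
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(c(lb, ub))))
  qa <- qr(t(A))                      # row space of A
  r <- qa$rank
  use_rows <- sort(qa$pivot[seq_len(r)])
  Ar <- A[use_rows, , drop = FALSE]
  br <- b[use_rows]
  if (r == 0) {
    # box only: vertices are all bound combinations -- only corners matter
    free <- which(ub - lb > tol)
    grid <- .bound_grid(lb, ub, free)
    ok <- apply(grid, 1, function(v) all(abs(A %*% v - b) <= tol))
    return(grid[ok, , drop = FALSE])
  }
  if (choose(n, r) > max_bases)
    stop("enumeration infeasible: choose(", n, ", ", r, ") bases")
  bases <- combn(n, r)
  verts <- list()
  for (k in seq_len(ncol(bases))) {
    B <- bases[, k]
    AB <- Ar[, B, drop = FALSE]
    qb <- qr(AB)
    if (qb$rank < r) next
    N <- setdiff(seq_len(n), B)
    XN <- .bound_grid(lb[N], ub[N], which(ub[N] - lb[N] > tol))
    if (nrow(XN) > 4096) stop("enumeration infeasible: too many bound combos")
    RHS <- br - if (length(N)) Ar[, N, drop = FALSE] %*% t(XN) else
      matrix(0, r, 1)
    XB <- matrix(qr.coef(qb, RHS), nrow = r)
    for (q in seq_len(ncol(XB))) {
      xb <- XB[, q]
      if (any(xb < lb[B] - tol) || any(xb > ub[B] + tol)) next
      v <- numeric(n)
      v[B] <- pmin(pmax(xb, lb[B]), ub[B])
      if (length(N)) v[N] <- XN[q, ]
      if (max(abs(A %*% v - b)) > max(tol, 1e-7)) next
      verts[[length(verts) + 1L]] <- v
    }
  }
  if (!length(verts)) return(matrix(numeric(), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 7)), , drop = FALSE]
}

# all combinations of lb/ub values over the free coordinates; fixed
# coordinates sit at lb
.bound_grid <- function(lb, ub, free) {
  n <- length(lb)
  base <- matrix(lb, nrow = 1)
  if (!length(free)) return(base)
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(free))))
  out <- base[rep(1, nrow(combos)), , drop = FALSE]
  for (i in seq_along(free)) out[combos[, i], free[i]] <- ub[free[i]]
  out
}

#' FBA by exhaustive enumeration (oracle)
#'
#' @inheritParams solve_fba
#' @return list with `status`, `objective_value` and the optimal vertex
#'   `fluxes` (named).
#' @export
fba_by_enumeration <- function(model, objective = NULL,
                               direction = c("max", "min")) {
  direction <- match.arg(direction)
  c_ <- .objective_vector(model, objective)
  lp <- .lp_parts(model)
  V <- enumerate_vertices(lp$A, lp$b, lp$lb, lp$ub)
  if (!nrow(V))
    return(list(status = "infeasible", objective_value = NA_real_,
                fluxes = NULL))
  vals <- as.numeric(V %*% c_)
  k <- if (direction == "max") which.max(vals) else which.min(vals)
  list(status = "optimal", objective_value = vals[k],
       fluxes = setNames(V[k, ], lp$rxn))
}

#' FVA by exhaustive enumeration (oracle)
#'
#' Enumerates the vertices of the polytope augmented with the
#' fraction-of-optimum objective constraint and reads off per-reaction
#' coordinate ranges.
#'
#' @inheritParams flux_variability
#' @return data.frame with `reaction`, `min`, `max`.
#' @export
fva_by_enumeration <- function(model, reactions = NULL, objective = NULL,
                               fraction_of_optimum = 1,
                               direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.null(reactions)) reactions <- model$reactions$id
  c_ <- .objective_vector(model, objective)
  base <- fba_by_enumeration(model, objective, direction)
  if (base$status != "optimal") stop("model infeasible")
  lp <- .fva_lp(model, c_, base$objective_value, fraction_of_optimum,
                direction)
  V <- enumerate_vertices(lp$A, lp$b, lp$lb, lp$ub)
  if (!nrow(V)) stop("augmented polytope empty")
  idx <- match(reactions, .lp_parts(model)$rxn)
  data.frame(reaction = reactions,
             min = apply(V[, idx, drop = FALSE], 2, min),
             max = apply(V[, idx, drop = FALSE], 2, max))
}
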