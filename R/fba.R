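# Constraint-based optimization on metabolic_model objects: FBA with
# parsimonious flux resolution, flux variability analysis, robustness scans,
# single-gene deletions and flux coupling constraints.

# Assemble the LP pieces shared by the simplex path and the enumeration
# oracle: steady-state rows for non-boundary metabolites plus one
# homogeneous row per flux coupling (v_target - ratio * v_source = 0).
.lp_parts <- function(model, extra_rows = NULL, extra_rhs = NULL) {
  keep <- !model$metabolites$boundary
  A <- as.matrix(model$S[keep, , drop = FALSE])
  rn <- model$metabolites$id[keep]
  cp <- model$couplings
  if (nrow(cp)) {
    C <- matrix(0, nrow(cp), ncol(A))
    for (i in seq_len(nrow(cp))) {
      C[i, match(cp$target[i], model$reactions$id)] <- 1
      C[i, match(cp$source[i], model$reactions$id)] <- -cp$ratio[i]
    }
    A <- rbind(A, C)
    rn <- c(rn, paste0("coupling_", seq_len(nrow(cp))))
  }
  b <- numeric(nrow(A))
  if (!is.null(extra_rows)) {
    A <- rbind(A, extra_rows)
    b <- c(b, extra_rhs)
    rn <- c(rn, paste0("extra_", seq_len(NROW(extra_rows))))
  }
  rownames(A) <- rn
  list(A = A, b = b,
       lb = model$reactions$lb, ub = model$reactions$ub,
       rxn = model$reactions$id)
}

.objective_vector <- function(model, objective = NULL) {
  n <- nrow(model$reactions)
  if (is.null(objective)) {
    c_ <- model$reactions$objective
    if (all(c_ == 0)) stop("model has no objective; pass `objective`")
    return(c_)
  }
  if (is.character(objective)) {
    miss <- setdiff(objective, model$reactions$id)
    if (length(miss)) stop("objective reaction not in model: ", miss[1])
    c_ <- numeric(n)
    c_[match(objective, model$reactions$id)] <- 1
    return(c_)
  }
  if (is.numeric(objective) && !is.null(names(objective))) {
    miss <- setdiff(names(objective), model$reactions$id)
    if (length(miss)) stop("objective reaction not in model: ", miss[1])
    c_ <- numeric(n)
    c_[match(names(objective), model$reactions$id)] <- objective
    return(c_)
  }
  stop("objective must be reaction id(s) or a named numeric vector")
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the objective `c'v` subject to steady state
#' `S v = 0`, the flux bounds, and any coupling constraints. With
#' `parsimonious = TRUE` the objective is fixed at its optimum and the total
#' absolute flux is minimised before fluxes are reported, which removes the
#' degeneracy of alternate optima; the headline objective value is identical
#' either way.
#'
#' @param model a [metabolic_model].
#' @param objective reaction id(s) or named weight vector; `NULL` uses the
#'   model's stored objective.
#' @param direction `"max"` or `"min"`.
#' @param parsimonious resolve alternate optima by total-flux minimisation.
#' @return a `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"numerical"`), `objective_value`, named `fluxes`,
#'   `parsimonious` flag and the steady-state `residual`.
#' @export
solve_fba <- function(model, objective = NULL,
                      direction = c("max", "min"), parsimonious = FALSE) {
  direction <- match.arg(direction)
  c_ <- .objective_vector(model, objective)
  lp <- .lp_parts(model)
  res <- solve_lp(c_, lp$A, lp$b, lp$lb, lp$ub,
                  maximize = direction == "max")
  sol <- list(status = res$status,
              objective_value = res$objective,
              fluxes = NULL, parsimonious = FALSE,
              direction = direction, residual = NA_real_)
  class(sol) <- "flux_solution"
  if (res$status != "optimal") return(sol)
  v <- res$x
  if (parsimonious) {
    v2 <- .pfba_fluxes(lp, c_, res$objective)
    if (!is.null(v2)) { v <- v2; sol$parsimonious <- TRUE }
  }
  sol$fluxes <- setNames(v, lp$rxn)
  sol$residual <- max(abs(lp$A %*% v - lp$b))
  sol
}

# second-stage LP: fix c'v at the incumbent optimum, minimise sum |v| via a
# v = p - q split (p, q >= 0); returns the structural flux vector
.pfba_fluxes <- function(lp, c_, opt) {
  n <- length(lp$lb)
  Ap <- cbind(lp$A, -lp$A)
  Ap <- rbind(Ap, c(c_, -c_))
  bp <- c(lp$b, opt)
  lbp <- c(pmax(lp$lb, 0), pmax(-lp$ub, 0))
  ubp <- c(pmax(lp$ub, 0), pmax(-lp$lb, 0))
  res <- solve_lp(rep(1, 2 * n), Ap, bp, lbp, ubp, maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)] - res$x[n + seq_len(n)]
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status)
  if (x$status == "optimal") {
    cat(sprintf("  objective (%s) = %.6g", x$direction, x$objective_value))
    if (x$parsimonious) cat("  [parsimonious]")
    cat(sprintf("  ||S.v||_inf = %.2e", x$residual))
  }
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective being held
#' at at least `fraction_of_optimum` of its optimal value (for minimisation
#' objectives: at most `optimum / fraction`).
#'
#' @inheritParams solve_fba
#' @param reactions reaction ids to scan; `NULL` scans all.
#' @param fraction_of_optimum fraction in (0, 1].
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, reactions = NULL, objective = NULL,
                             fraction_of_optimum = 1,
                             direction = c("max", "min")) {
  direction <- match.arg(direction)
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  if (is.null(reactions)) reactions <- model$reactions$id
  miss <- setdiff(reactions, model$reactions$id)
  if (length(miss)) stop("unknown reaction: ", miss[1])
  c_ <- .objective_vector(model, objective)
  base <- solve_fba(model, objective, direction)
  if (base$status != "optimal")
    stop("model infeasible; cannot run FVA at fraction ",
         fraction_of_optimum)
  opt <- base$objective_value
  lp <- .fva_lp(model, c_, opt, fraction_of_optimum, direction)
  n <- length(lp$lb) - 1L  # last column is the slack
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], model$reactions$id)
    cj <- numeric(n + 1L); cj[j] <- 1
    lo <- solve_lp(cj, lp$A, lp$b, lp$lb, lp$ub, maximize = FALSE)
    hi <- solve_lp(cj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for reaction ", reactions[k],
           " at fraction ", fraction_of_optimum)
    out$min[k] <- lo$objective
    out$max[k] <- hi$objective
  }
  attr(out, "fraction_of_optimum") <- fraction_of_optimum
  attr(out, "optimum") <- opt
  out
}

# LP with the objective constrained to its optimal band via a slack column:
#   max direction: c'v - s = f * opt,  s in [0, (1-f)*|opt| + 1]
#   min direction: c'v + s = opt / f   (objective may use up the band)
.fva_lp <- function(model, c_, opt, fraction, direction) {
  lp <- .lp_parts(model)
  n <- length(lp$lb)
  slack_ub <- abs(opt) * (1 / min(fraction, 1) - fraction) + abs(opt) + 1
  if (direction == "max") {
    row <- c(c_, -1)
    rhs <- fraction * opt
  } else {
    row <- c(c_, 1)
    rhs <- if (opt >= 0) opt / fraction else opt * fraction
  }
  A <- rbind(cbind(lp$A, 0), row)
  b <- c(lp$b, rhs)
  list(A = A, b = b, lb = c(lp$lb, 0), ub = c(lp$ub, slack_ub))
}

#' Robustness scan over a control reaction's uptake bound
#'
#' For each grid value the uptake bound of `control_reaction` (an exchange;
#' grid values are positive uptake magnitudes) is set and each objective's
#' optimum recorded, together with designated reporter fluxes from the
#' parsimonious solution of the first objective. Infeasible grid points are
#' recorded with their status and the scan continues.
#'
#' @param model a [metabolic_model].
#' @param control_reaction exchange reaction id whose uptake is scanned.
#' @param grid strictly monotone vector of uptake magnitudes (mmol/gDW/h).
#' @param objectives list of objective specs (each as in [solve_fba()]); a
#'   single spec is also accepted.
#' @param reporters reaction ids whose fluxes to record at each grid point.
#' @param fix if `TRUE` the uptake is fixed (`lb = ub = -grid`); default
#'   caps it (`lb = -grid`).
#' @return data.frame (class `robustness_curve`) with one row per grid
#'   point: `bound`, `status`, one `objective_<id>` column per objective and
#'   one `flux_<id>` column per reporter.
#' @export
robustness_scan <- function(model, control_reaction, grid, objectives,
                            reporters = character(), fix = FALSE) {
  if (!control_reaction %in% model$reactions$id)
    stop("unknown reaction: ", control_reaction)
  if (length(grid) > 1 && !(all(diff(grid) > 0) || all(diff(grid) < 0)))
    stop("grid must be strictly monotone")
  if (!is.list(objectives)) objectives <- list(objectives)
  obj_names <- vapply(objectives, function(o)
    if (is.character(o)) paste(o, collapse = "+") else paste(names(o), collapse = "+"),
    character(1))
  out <- data.frame(bound = grid, status = NA_character_)
  for (nm in obj_names) out[[paste0("objective_", nm)]] <- NA_real_
  for (rp in reporters) out[[paste0("flux_", rp)]] <- NA_real_
  for (i in seq_along(grid)) {
    m <- apply_edits(model, edit_set_bounds(
      control_reaction, lb = -grid[i], ub = if (fix) -grid[i] else NULL))
    first <- TRUE
    for (k in seq_along(objectives)) {
      sol <- solve_fba(m, objectives[[k]], "max",
                       parsimonious = first && length(reporters) > 0)
      if (first) {
        out$status[i] <- sol$status
        if (sol$status == "optimal")
          for (rp in reporters)
            out[[paste0("flux_", rp)]][i] <- sol$fluxes[[rp]]
        first <- FALSE
      }
      if (sol$status == "optimal")
        out[[paste0("objective_", obj_names[k])]][i] <- sol$objective_value
    }
  }
  class(out) <- c("robustness_curve", class(out))
  attr(out, "control_reaction") <- control_reaction
  out
}

#' Single-gene deletion screen
#'
#' Evaluates every GPR rule with each gene in turn set to `FALSE`; reactions
#' whose rule fails are closed (bounds 0) and growth re-optimised. Genes
#' absent from every rule have ratio 1 by construction.
#'
#' @param model a [metabolic_model].
#' @param objective growth objective (default: the model's).
#' @param essential_cutoff wild-type-relative growth ratio below which a
#'   gene is classed essential.
#' @return data.frame with `gene`, `growth_ratio`, `essential`.
#' @export
single_gene_deletions <- function(model, objective = NULL,
                                  essential_cutoff = 0.01) {
  wt <- solve_fba(model, objective, "max")
  if (wt$status != "optimal") stop("wild-type model does not solve")
  mu0 <- wt$objective_value
  genes <- model$genes
  rules <- model$reactions$gene_rule
  has_rule <- nzchar(rules)
  out <- data.frame(gene = genes, growth_ratio = NA_real_)
  for (g in seq_along(genes)) {
    hit <- which(has_rule & vapply(rules, function(r)
      genes[g] %in% gpr_genes(r), logical(1)))
    off <- hit[!vapply(rules[hit], gpr_eval, logical(1),
                       knockouts = genes[g])]
    if (!length(off)) { out$growth_ratio[g] <- 1; next }
    m <- model
    m$reactions$lb[off] <- 0
    m$reactions$ub[off] <- 0
    sol <- solve_fba(m, objective, "max")
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    out$growth_ratio[g] <- if (mu0 > 0) max(0, min(1, mu / mu0)) else 1
  }
  out$essential <- out$growth_ratio < essential_cutoff
  attr(out, "essential_cutoff") <- essential_cutoff
  out
}

#' Add a flux coupling constraint
#'
#' Appends the homogeneous constraint `v[target] == ratio * v[source]`,
#' honoured by every subsequent solve regardless of objective.
#'
#' @param model a [metabolic_model].
#' @param target,source reaction ids (must differ).
#' @param ratio dimensionless, finite.
#' @return the model with the coupling added.
#' @export
couple_fluxes <- function(model, target, source, ratio) {
  if (identical(target, source))
    stop("cannot couple a reaction to itself: ", target)
  apply_edits(model, edit_add_coupling(target, source, ratio))
}

# ---- uptake helpers (positive-magnitude API over negative uptake flux) ----

#' Set the uptake rate of an exchange reaction
#'
#' @param model a [metabolic_model].
#' @param exchange exchange reaction id.
#' @param rate positive uptake magnitude in mmol/gDW/h.
#' @param fix if `TRUE` the uptake is fixed exactly (`lb = ub = -rate`);
#'   otherwise `-rate` becomes the lower bound (an uptake cap).
#' @return the modified model.
#' @export
set_uptake <- function(model, exchange, rate, fix = FALSE) {
  stopifnot(rate >= 0)
  apply_edits(model, edit_set_bounds(
    exchange, lb = -rate, ub = if (fix) -rate else NULL))
}

#' Close all exchange reactions' uptake
#'
#' Sets every exchange lower bound to 0 (no uptake; excretion unchanged),
#' except those listed in `keep_open`.
#'
#' @param model a [metabolic_model].
#' @param keep_open exchange ids left untouched.
#' @return the modified model.
#' @export
close_uptakes <- function(model, keep_open = character()) {
  kinds <- reaction_kinds(model)
  ex <- model$reactions$id[kinds == "exchange"]
  for (id in setdiff(ex, keep_open))
    model <- apply_edits(model, edit_set_bounds(id, lb = 0))
  model
}

#' Uptake magnitude of an exchange flux in a solution
#'
#' @param solution a `flux_solution`.
#' @param exchange exchange reaction id.
#' @return positive uptake magnitude (0 when the flux is excretion).
#' @export
uptake_rate <- function(solution, exchange) {
  v <- solution$fluxes[[exchange]]
  if (is.null(v)) stop("no flux recorded for ", exchange)
  max(0, -v)
}
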