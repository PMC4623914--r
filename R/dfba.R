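# Dynamic FBA: static-optimization batch simulation. Between successive
# steady-state solves the biomass grows exponentially at the current mu and
# extracellular concentrations are integrated with the exact exponential
# weight, so concentrations follow explicit Euler in the bounds and the
# scheme converges at first order in dt.

.DEFAULT_MW <- c(glucose = 180.16, glycerol = 92.09)

# g/mol weight for the species behind an exchange reaction
.exchange_mw <- function(model, exchange, mw_override = NULL) {
  if (!is.null(mw_override) && exchange %in% names(mw_override))
    return(mw_override[[exchange]])
  j <- match(exchange, model$reactions$id)
  if (is.na(j)) stop("unknown exchange: ", exchange)
  part <- which(model$S[, j] != 0 & !model$metabolites$boundary)
  if (length(part) != 1)
    stop(exchange, " is not a single-species exchange reaction")
  wt <- formula_weight(model$metabolites$formula[part])
  if (is.na(wt)) {
    nm <- tolower(model$metabolites$name[part])
    hit <- names(.DEFAULT_MW)[vapply(names(.DEFAULT_MW), grepl, logical(1),
                                     x = nm)]
    if (length(hit)) return(.DEFAULT_MW[[hit[1]]])
    stop("no molecular weight available for ", exchange,
         "; pass it via `mw`")
  }
  wt
}

#' Simulate batch growth by dynamic FBA
#'
#' Per step, each tracked exchange's uptake bound is the smaller of its
#' kinetic cap and what the remaining extracellular pool can supply over
#' `dt`; FBA (growth maximisation) is solved; biomass is updated as
#' `X * exp(mu dt)` and concentrations by `flux * MW * integral(X)`. The
#' run stops at substrate exhaustion, infeasibility or `t_end`.
#'
#' @param model a [metabolic_model].
#' @param biomass0 initial biomass, g/L (> 0).
#' @param concentrations named initial concentrations (g/L) keyed by
#'   exchange reaction id; these exchanges are tracked dynamically.
#' @param uptake_caps named maximal specific uptake rates (mmol/gDW/h); the
#'   caps name the limiting substrates.
#' @param dt step, h.
#' @param t_end horizon, h.
#' @param objective growth objective (default: the model's).
#' @param mw named g/mol overrides keyed by exchange id (otherwise taken
#'   from metabolite formulas, with glucose/glycerol fallbacks).
#' @return a `batch_trajectory`: data.frame with `time`, `biomass` and one
#'   column per tracked exchange; attribute `terminal_reason` is one of
#'   `"substrate_exhausted"`, `"t_end"`, `"infeasible"`.
#' @export
simulate_batch <- function(model, biomass0, concentrations, uptake_caps,
                           dt = 0.1, t_end = 48, objective = NULL,
                           mw = NULL) {
  stopifnot(biomass0 > 0, dt > 0, t_end >= 0)
  exch <- names(concentrations)
  miss <- setdiff(union(exch, names(uptake_caps)), model$reactions$id)
  if (length(miss)) stop("unknown exchange: ", miss[1])
  wt <- vapply(exch, .exchange_mw, numeric(1), model = model,
               mw_override = mw)
  limiting <- intersect(names(uptake_caps), exch)
  X <- biomass0
  conc <- unlist(concentrations)
  t <- 0
  rows <- list(c(time = 0, biomass = X, conc))
  reason <- "t_end"
  if (length(limiting) && all(conc[limiting] <= 1e-9)) {
    reason <- "substrate_exhausted"
    t_end <- 0
  }
  while (t < t_end - 1e-12) {
    step <- min(dt, t_end - t)
    m <- model
    for (e in exch) {
      avail <- 1000 * conc[[e]] / wt[[e]] / (X * step)  # mmol/gDW/h
      cap <- if (e %in% names(uptake_caps)) uptake_caps[[e]] else Inf
      j <- match(e, m$reactions$id)
      m$reactions$lb[j] <- max(m$reactions$lb[j], -min(cap, avail, 1000))
    }
    sol <- solve_fba(m, objective, "max")
    if (sol$status != "optimal") { reason <- "infeasible"; break }
    mu <- max(0, sol$objective_value)
    growth_int <- if (mu > 1e-12) X * (exp(mu * step) - 1) / mu else X * step
    for (e in exch)
      conc[[e]] <- max(0, conc[[e]] + sol$fluxes[[e]] * wt[[e]] / 1000 *
                         growth_int)
    X <- X * exp(mu * step)
    t <- t + step
    rows[[length(rows) + 1L]] <- c(time = t, biomass = X, conc)
    if (length(limiting) && all(conc[limiting] <= 1e-9) && mu <= 1e-9) {
      reason <- "substrate_exhausted"
      break
    }
  }
  traj <- as.data.frame(do.call(rbind, rows))
  class(traj) <- c("batch_trajectory", class(traj))
  attr(traj, "terminal_reason") <- reason
  traj
}

#' Yields from a batch trajectory
#'
#' Biomass yield `Y_SX = dX / dS` (g biomass per g substrate consumed) and,
#' per product column, `dP / dS`.
#'
#' @param traj a `batch_trajectory`.
#' @param substrate tracked exchange id of the consumed substrate.
#' @param products tracked exchange ids of excreted products.
#' @return list with `Y_SX`, `consumed` (g/L) and `product_yields`.
#' @export
trajectory_yields <- function(traj, substrate, products = character()) {
  stopifnot(substrate %in% names(traj))
  n <- nrow(traj)
  consumed <- traj[[substrate]][1] - traj[[substrate]][n]
  if (consumed <= 0) stop("no net consumption of ", substrate)
  ysx <- (traj$biomass[n] - traj$biomass[1]) / consumed
  py <- vapply(products, function(p)
    (traj[[p]][n] - traj[[p]][1]) / consumed, numeric(1))
  list(Y_SX = ysx, consumed = consumed, product_yields = py)
}
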