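# Lipid-accumulation scenario analyses: lipogenesis-phase optimization,
# fed-batch feed-rate calculation, TAG-content scans, oxygen-uptake
# thresholds, NADPH-source comparison, theoretical yields and substrate
# growth screening.

#' Map of scenario-relevant reactions and metabolites
#'
#' Scenario functions are model-agnostic; this map names the handful of
#' reactions and cofactor species they need. Entries prefixed `~` are
#' treated as regular expressions and resolved against the model with
#' [resolve_map()]. `toy_map()` matches the bundled synthetic core model.
#'
#' @param growth,lipid,glucose,o2,co2,citrate,pyruvate,acl,ppp,atpase
#'   reaction ids (or `~regex`).
#' @param nadph,accoa,atp,adp metabolite ids (or `~regex`, possibly
#'   matching several compartments).
#' @param tag TAG pseudo-species metabolite id.
#' @return named list of class `scenario_map`.
#' @export
scenario_map <- function(growth, lipid, glucose, o2, co2, citrate,
                         pyruvate = NA, acl = NA, ppp = NA,
                         atpase = "ATPM", nadph, accoa = NA,
                         atp = NA, adp = NA, tag = NA) {
  structure(list(growth = growth, lipid = lipid, glucose = glucose,
                 o2 = o2, co2 = co2, citrate = citrate,
                 pyruvate = pyruvate, acl = acl, ppp = ppp,
                 atpase = atpase, nadph = nadph, accoa = accoa,
                 atp = atp, adp = adp, tag = tag),
            class = "scenario_map")
}

#' @rdname scenario_map
#' @export
toy_map <- function() {
  scenario_map(growth = "BIOMASS", lipid = "DM_tag", glucose = "EX_glc",
               o2 = "EX_o2", co2 = "EX_co2", citrate = "EX_cit",
               pyruvate = "EX_pyr", acl = "ACL", ppp = "PPP",
               atpase = "ATPM", nadph = "nadph_c", accoa = "accoa_c",
               atp = "atp_c", adp = "adp_c", tag = "tag_c")
}

#' @rdname scenario_map
#' @param map a `scenario_map` possibly holding `~regex` entries.
#' @param model model against which to resolve.
#' @export
resolve_map <- function(map, model) {
  ids <- c(model$reactions$id, model$metabolites$id)
  out <- lapply(map, function(entry) {
    if (length(entry) == 1 && !is.na(entry) && startsWith(entry, "~")) {
      hit <- grep(sub("^~", "", entry), ids, value = TRUE)
      if (!length(hit)) NA_character_ else hit
    } else entry
  })
  class(out) <- "scenario_map"
  out
}

#' Net production rate of a metabolite pool
#'
#' Sums, over all reactions, the positive net production of the listed
#' species at the given fluxes — e.g. the cellular NADPH or acetyl-CoA
#' synthesis rate of a flux solution.
#'
#' @param model a [metabolic_model].
#' @param fluxes named flux vector (from a `flux_solution`).
#' @param mets metabolite ids forming the pool.
#' @return production rate in mmol/gDW/h.
#' @export
production_rate <- function(model, fluxes, mets) {
  rows <- match(mets, model$metabolites$id)
  rows <- rows[!is.na(rows)]
  if (!length(rows)) return(NA_real_)
  per_rxn <- as.numeric(Matrix::colSums(model$S[rows, , drop = FALSE])) *
    fluxes[model$reactions$id]
  sum(pmax(0, per_rxn))
}
.production_rate <- production_rate

#' Constraints describing the lipogenesis (nitrogen-starved) phase
#'
#' @param substrate_uptake measured specific uptake, mmol/gDW/h.
#' @param citrate measured citrate excretion: interpreted per
#'   `citrate_mode` as mol per mol substrate (`"per_substrate"`) or as an
#'   absolute flux (`"absolute"`); `NULL` leaves citrate unconstrained.
#' @param citrate_mode see `citrate`.
#' @param growth growth rate during the phase (0 for full N starvation).
#' @return list of class `lipogenesis_constraints`.
#' @export
lipogenesis_constraints <- function(substrate_uptake = 0.35,
                                    citrate = NULL,
                                    citrate_mode = c("per_substrate",
                                                     "absolute"),
                                    growth = 0) {
  citrate_mode <- match.arg(citrate_mode)
  stopifnot(substrate_uptake >= 0, growth >= 0,
            is.null(citrate) || citrate >= 0)
  structure(list(substrate_uptake = substrate_uptake, citrate = citrate,
                 citrate_mode = citrate_mode, growth = growth),
            class = "lipogenesis_constraints")
}

.apply_lipogenesis <- function(model, constraints, map) {
  m <- apply_edits(model, list(
    edit_set_bounds(map$growth, lb = constraints$growth,
                    ub = constraints$growth),
    edit_set_bounds(map$glucose, lb = -constraints$substrate_uptake,
                    ub = -constraints$substrate_uptake)))
  if (!is.null(constraints$citrate)) {
    cit <- if (constraints$citrate_mode == "per_substrate")
      constraints$citrate * constraints$substrate_uptake
    else constraints$citrate
    m <- apply_edits(m, edit_set_bounds(map$citrate, lb = cit, ub = cit))
  }
  m
}

#' Model with the lipogenesis-phase constraints applied
#'
#' Pins growth, substrate uptake and (optionally) citrate excretion at the
#' measured values and returns the constrained model, e.g. for FVA around
#' the lipogenesis optimum.
#'
#' @inheritParams lipogenesis_fba
#' @return the constrained [metabolic_model].
#' @export
lipogenesis_model <- function(model,
                              constraints = lipogenesis_constraints(),
                              map) {
  map <- resolve_map(map, model)
  .apply_lipogenesis(model, constraints, map)
}

#' Maximise lipid accumulation under lipogenesis-phase constraints
#'
#' Growth is pinned at the measured (usually zero) rate, substrate uptake
#' and citrate excretion fixed at their measured values, and the TAG demand
#' flux maximised, with parsimonious flux resolution. Key reporter rates
#' (ATP:citrate lyase, PPP entry, NADPH and acetyl-CoA production) are
#' extracted via the map.
#'
#' @param model a [metabolic_model] (with NGAM coupling in place if the
#'   maintenance model is wanted).
#' @param constraints a [lipogenesis_constraints].
#' @param map a [scenario_map] (resolved against the model).
#' @return list with the `flux_solution` and the reporter rates
#'   `lipid_flux`, `acl_flux`, `ppp_flux`, `nadph_production`,
#'   `accoa_production`.
#' @export
lipogenesis_fba <- function(model, constraints = lipogenesis_constraints(),
                            map) {
  map <- resolve_map(map, model)
  m <- .apply_lipogenesis(model, constraints, map)
  sol <- solve_fba(m, map$lipid, "max", parsimonious = TRUE)
  if (sol$status != "optimal")
    stop("lipogenesis problem ", sol$status,
         " (check uptake/citrate/growth constraints)")
  v <- sol$fluxes
  list(solution = sol,
       lipid_flux = sol$objective_value,
       acl_flux = if (!is.na(map$acl[1])) v[[map$acl[1]]] else NA_real_,
       ppp_flux = if (!is.na(map$ppp[1])) v[[map$ppp[1]]] else NA_real_,
       nadph_production = .production_rate(m, v, map$nadph),
       accoa_production = .production_rate(m, v, map$accoa))
}

#' Minimal substrate uptake sustaining a target lipid flux
#'
#' With citrate excretion closed and growth at zero, finds the smallest
#' substrate uptake for which the lipid flux can reach `target_lipid_flux`
#' (NGAM coupling, if present, stays in force). This is the uptake a
#' fed-batch feed should deliver so that no overflow citrate is produced.
#'
#' @param model a [metabolic_model].
#' @param target_lipid_flux mmol/gDW/h TAG demand to sustain.
#' @param map a [scenario_map].
#' @return minimal uptake, mmol/gDW/h.
#' @export
compute_feed_uptake <- function(model, target_lipid_flux, map) {
  stopifnot(target_lipid_flux >= 0)
  map <- resolve_map(map, model)
  lipid_ub <- model$reactions$ub[match(map$lipid[1], model$reactions$id)]
  m <- apply_edits(model, list(
    edit_set_bounds(map$growth, lb = 0, ub = 0),
    edit_set_bounds(map$citrate, lb = 0, ub = 0),
    edit_set_bounds(map$glucose, lb = -1000, ub = 0),
    edit_set_bounds(map$lipid, lb = target_lipid_flux,
                    ub = max(lipid_ub, target_lipid_flux))))
  # uptake flux is negative: maximising it minimises the uptake magnitude
  sol <- solve_fba(m, map$glucose, "max")
  if (sol$status != "optimal")
    stop("lipid target ", target_lipid_flux,
         " unreachable at any uptake (status ", sol$status, ")")
  max(0, -sol$objective_value)
}

#' Fed-batch feed schedule from a target uptake rate
#'
#' Dimensional identity: the pump must deliver
#' `target_uptake * biomass * MW` grams of substrate per hour.
#'
#' @param target_uptake specific uptake to sustain, mmol/gDW/h.
#' @param biomass culture biomass, g.
#' @param feed_concentration substrate concentration of the feed, g/L.
#' @param substrate_mw substrate molecular weight, g/mol.
#' @return list of class `feed_plan` with `delivery_g_h`, `pump_rate_L_h`,
#'   `pump_rate_uL_min`.
#' @export
feed_schedule <- function(target_uptake, biomass, feed_concentration,
                          substrate_mw = 180.16) {
  stopifnot(target_uptake >= 0, biomass > 0, feed_concentration > 0,
            substrate_mw > 0)
  delivery <- target_uptake * biomass * substrate_mw / 1000  # g/h
  pump_L_h <- delivery / feed_concentration
  structure(list(target_uptake = target_uptake, biomass = biomass,
                 feed_concentration = feed_concentration,
                 substrate_mw = substrate_mw,
                 delivery_g_h = delivery,
                 pump_rate_L_h = pump_L_h,
                 pump_rate_uL_min = pump_L_h * 1e6 / 60),
            class = "feed_plan")
}

#' Substrate delivery of a feed pump
#'
#' @param feed_concentration g/L.
#' @param pump_rate_uL_min pump rate, uL/min.
#' @return delivery in g/h.
#' @export
feed_delivery <- function(feed_concentration, pump_rate_uL_min) {
  feed_concentration * pump_rate_uL_min * 1e-6 * 60
}

#' Scan metabolic fluxes over the biomass lipid fraction
#'
#' Rebuilds the biomass equation for each lipid fraction and solves either
#' with a fixed substrate uptake and growth maximisation
#' (`mode = "fixed_uptake"`) or with a fixed growth rate and uptake
#' minimisation (`mode = "fixed_growth"`). Records growth/uptake, O2
#' uptake, CO2 output, respiratory quotient, ATP:citrate-lyase flux and
#' NADPH production per point.
#'
#' @param model a [metabolic_model].
#' @param spec0 the reference [biomass_spec]; only `f_NL` is varied.
#'   `NULL` rescales the model's existing biomass equation in place via
#'   [rescale_biomass_lipid()] (for models whose composition comes from
#'   the model file).
#' @param f_grid lipid fractions to scan (within [0.004, 0.80]).
#' @param mode `"fixed_uptake"` or `"fixed_growth"`.
#' @param map a [scenario_map].
#' @param uptake fixed substrate uptake (mmol/gDW/h) for
#'   `mode = "fixed_uptake"`.
#' @param growth fixed growth rate (1/h) for `mode = "fixed_growth"`.
#' @return data.frame (class `lipid_scan`) with one row per fraction.
#' @export
lipid_content_scan <- function(model, spec0, f_grid,
                               mode = c("fixed_uptake", "fixed_growth"),
                               map, uptake = 4, growth = 0.33) {
  mode <- match.arg(mode)
  map <- resolve_map(map, model)
  out <- data.frame(f_NL = f_grid, mu = NA_real_, uptake = NA_real_,
                    o2_uptake = NA_real_, co2_out = NA_real_,
                    rq = NA_real_, acl_flux = NA_real_,
                    nadph_production = NA_real_, status = NA_character_)
  for (i in seq_along(f_grid)) {
    m <- if (is.null(spec0)) {
      rescale_biomass_lipid(model, f_grid[i], tag = map$tag,
                            id = map$growth)
    } else {
      spec <- spec0
      spec$f_NL <- f_grid[i]
      set_biomass(model, spec, tag = map$tag[1], atp = map$atp[1],
                  adp = map$adp[1], id = map$growth)
    }
    if (mode == "fixed_uptake") {
      m <- apply_edits(m, edit_set_bounds(map$glucose, lb = -uptake,
                                          ub = -uptake))
      sol <- solve_fba(m, map$growth, "max", parsimonious = TRUE)
    } else {
      m <- apply_edits(m, list(
        edit_set_bounds(map$growth, lb = growth, ub = growth),
        edit_set_bounds(map$glucose, lb = -1000, ub = 0)))
      sol <- solve_fba(m, map$glucose, "max", parsimonious = TRUE)
    }
    out$status[i] <- sol$status
    if (sol$status != "optimal") next
    v <- sol$fluxes
    out$mu[i] <- if (mode == "fixed_uptake") sum(v[map$growth]) else growth
    out$uptake[i] <- max(0, -v[[map$glucose]])
    out$o2_uptake[i] <- max(0, -v[[map$o2]])
    out$co2_out[i] <- max(0, v[[map$co2]])
    out$rq[i] <- if (out$o2_uptake[i] > 1e-9)
      out$co2_out[i] / out$o2_uptake[i] else NA_real_
    out$acl_flux[i] <- if (!is.na(map$acl[1])) v[[map$acl[1]]] else NA_real_
    out$nadph_production[i] <- .production_rate(m, v, map$nadph)
  }
  class(out) <- c("lipid_scan", class(out))
  attr(out, "mode") <- mode
  out
}

# ---- NADPH sources --------------------------------------------------------

#' Reactions able to produce NADPH
#'
#' Scans the stoichiometry for reactions that can net-produce any of the
#' NADPH species in their allowed flux direction.
#'
#' @param model a [metabolic_model].
#' @param nadph_mets NADPH metabolite ids.
#' @return data.frame with `reaction`, `coef` (net NADPH stoichiometry) and
#'   `direction` (`"forward"` or `"reverse"`).
#' @export
nadph_producers <- function(model, nadph_mets) {
  rows <- match(nadph_mets, model$metabolites$id)
  rows <- rows[!is.na(rows)]
  if (!length(rows)) stop("no NADPH species found in model")
  net <- as.numeric(Matrix::colSums(model$S[rows, , drop = FALSE]))
  fwd <- which(net > 0 & model$reactions$ub > 0)
  rev <- which(net < 0 & model$reactions$lb < 0)
  data.frame(
    reaction = c(model$reactions$id[fwd], model$reactions$id[rev]),
    coef = c(net[fwd], net[rev]),
    direction = c(rep("forward", length(fwd)), rep("reverse", length(rev))),
    stringsAsFactors = FALSE)
}

#' Restrict NADPH generation to one source
#'
#' Bounds the NADPH-producing direction of every reaction outside the
#' chosen source set to zero (forward producers get `ub = 0` capped at
#' their lower bound, reverse producers `lb = 0`). The original bounds are
#' kept in an attribute so [unrestrict_nadph()] can undo the restriction.
#'
#' @param model a [metabolic_model].
#' @param source reaction ids allowed to produce NADPH.
#' @param nadph_mets NADPH metabolite ids.
#' @return the restricted model.
#' @export
restrict_nadph_source <- function(model, source, nadph_mets) {
  prod <- nadph_producers(model, nadph_mets)
  if (!any(source %in% prod$reaction))
    stop("chosen source produces no NADPH in this model: ",
         paste(source, collapse = ", "))
  saved <- list()
  for (k in seq_len(nrow(prod))) {
    id <- prod$reaction[k]
    if (id %in% source) next
    j <- match(id, model$reactions$id)
    saved[[id]] <- c(lb = model$reactions$lb[j], ub = model$reactions$ub[j])
    if (prod$direction[k] == "forward")
      model$reactions$ub[j] <- max(0, model$reactions$lb[j])
    else
      model$reactions$lb[j] <- min(0, model$reactions$ub[j])
  }
  attr(model, "nadph_saved_bounds") <- saved
  model
}

#' @rdname restrict_nadph_source
#' @export
unrestrict_nadph <- function(model) {
  saved <- attr(model, "nadph_saved_bounds")
  if (is.null(saved)) return(model)
  for (id in names(saved)) {
    j <- match(id, model$reactions$id)
    model$reactions$lb[j] <- saved[[id]]["lb"]
    model$reactions$ub[j] <- saved[[id]]["ub"]
  }
  attr(model, "nadph_saved_bounds") <- NULL
  model
}

#' Resolve named NADPH source sets from an identifier-pattern file
#'
#' Reaction naming differs across reconstructions, so source membership is
#' declared as editable regex patterns (YAML mapping source name to a list
#' of case-insensitive patterns); the bundled file covers conventional
#' identifiers plus the synthetic core model.
#'
#' @param model a [metabolic_model].
#' @param patterns path to a YAML pattern file (default: the bundled one).
#' @return named list of reaction-id sets (possibly empty per source).
#' @export
nadph_source_sets <- function(model,
                              patterns = system.file(
                                "extdata", "nadph_sources.yaml",
                                package = "oleoflux")) {
  pat <- yaml::read_yaml(patterns)
  lapply(pat, function(ps)
    unique(unlist(lapply(ps, grep, x = model$reactions$id,
                         value = TRUE, ignore.case = TRUE))))
}

#' Compare lipid yields across NADPH sources
#'
#' For each named source set the model is restricted so that only that set
#' can generate NADPH, the lipogenesis optimum is recomputed, and the lipid
#' yield reported relative to the baseline source (by default the PPP).
#'
#' @param model a [metabolic_model], already containing any added
#'   alternative-source reactions (transhydrogenase, mannitol cycle, ...).
#' @param sources named list of reaction-id sets.
#' @param constraints a [lipogenesis_constraints].
#' @param map a [scenario_map].
#' @param baseline name of the reference source in `sources`.
#' @return data.frame with `source`, `lipid_flux`, `yield` (mmol TAG per
#'   mmol substrate) and `relative` (fraction of baseline yield).
#' @export
nadph_yield_comparison <- function(model, sources,
                                   constraints = lipogenesis_constraints(),
                                   map, baseline = "PPP") {
  stopifnot(baseline %in% names(sources))
  map <- resolve_map(map, model)
  res <- data.frame(source = names(sources), lipid_flux = NA_real_,
                    yield = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(sources)) {
    m <- restrict_nadph_source(model, sources[[i]], map$nadph)
    sol <- tryCatch(lipogenesis_fba(m, constraints, map),
                    error = function(e) NULL)
    if (is.null(sol)) next
    res$lipid_flux[i] <- sol$lipid_flux
    res$yield[i] <- sol$lipid_flux / constraints$substrate_uptake
  }
  ref <- res$yield[res$source == baseline]
  res$relative <- if (length(ref) && !is.na(ref) && ref > 0)
    res$yield / ref else NA_real_
  res
}

#' Maximal theoretical product yield
#'
#' Growth pinned to zero (and optionally NGAM switched off), substrate
#' uptake fixed at 1 mmol/gDW/h, product flux maximised: the optimum is the
#' mol/mol yield; the g/g yield uses the species' molecular weights.
#'
#' @param model a [metabolic_model].
#' @param product exchange or demand reaction id of the product.
#' @param substrate substrate exchange id.
#' @param map a [scenario_map] (for the growth/maintenance reactions).
#' @param ngam_off drop NGAM couplings for the calculation.
#' @param product_mw,substrate_mw g/mol (defaults from formulas).
#' @return list with `mol_per_mol`, `g_per_g` and a
#'   `percent_of_theoretical(observed_g_per_g)` closure.
#' @export
theoretical_yield <- function(model, product, substrate, map,
                              ngam_off = TRUE, product_mw = NULL,
                              substrate_mw = NULL) {
  map <- resolve_map(map, model)
  m <- apply_edits(model, list(
    edit_set_bounds(map$growth, lb = 0, ub = 0),
    edit_set_bounds(substrate, lb = -1, ub = -1)))
  if (ngam_off) {
    m$couplings <- m$couplings[m$couplings$target != map$atpase, ,
                               drop = FALSE]
    if (map$atpase %in% m$reactions$id)
      m <- apply_edits(m, edit_set_bounds(map$atpase, lb = 0))
  }
  sol <- solve_fba(m, product, "max")
  yield <- if (sol$status == "optimal") max(0, sol$objective_value) else 0
  if (yield == 0)
    message("theoretical_yield: product ", product,
            " unreachable from ", substrate)
  pmw <- product_mw
  if (is.null(pmw)) {
    j <- match(product, m$reactions$id)
    part <- which(m$S[, j] != 0 & !m$metabolites$boundary)
    pmw <- if (length(part) == 1)
      formula_weight(m$metabolites$formula[part]) else NA_real_
  }
  smw <- if (is.null(substrate_mw))
    .exchange_mw(m, substrate) else substrate_mw
  gpg <- yield * pmw / smw
  list(mol_per_mol = yield, g_per_g = gpg,
       percent_of_theoretical = function(observed_g_per_g)
         100 * observed_g_per_g / gpg)
}

#' Growth screen over candidate carbon substrates
#'
#' Every exchange uptake is closed except the free minimal-medium
#' exchanges; each substrate is opened in turn as sole carbon source and
#' growth predicted as `mu > threshold`. Substrates without an exchange in
#' the model are recorded untestable and excluded from the accuracy.
#'
#' @param model a [metabolic_model].
#' @param substrates exchange ids of candidate carbon sources.
#' @param truth named logical vector of observed growth per substrate.
#' @param free_exchanges exchanges left open (O2, CO2, minimal-medium
#'   ions, ...).
#' @param uptake uptake bound granted to the tested substrate.
#' @param threshold growth call cutoff on mu (1/h).
#' @param objective growth objective (default the model's).
#' @return data.frame of class `screen_report` with per-substrate calls;
#'   attributes `confusion` (TP/FP/TN/FN) and `accuracy`.
#' @export
substrate_screen <- function(model, substrates, truth, free_exchanges,
                             uptake = 10, threshold = 1e-6,
                             objective = NULL) {
  if (!length(substrates)) stop("empty substrate list")
  stopifnot(all(substrates %in% names(truth)))
  base <- close_uptakes(model, keep_open = free_exchanges)
  out <- data.frame(substrate = substrates, predicted = NA,
                    observed = unname(truth[substrates]),
                    testable = substrates %in% model$reactions$id)
  for (i in seq_along(substrates)) {
    if (!out$testable[i]) next
    m <- set_uptake(base, substrates[i], uptake)
    sol <- solve_fba(m, objective, "max")
    out$predicted[i] <- sol$status == "optimal" &&
      sol$objective_value > threshold
  }
  ok <- out$testable
  tp <- sum(out$predicted[ok] & out$observed[ok])
  fp <- sum(out$predicted[ok] & !out$observed[ok])
  tn <- sum(!out$predicted[ok] & !out$observed[ok])
  fn <- sum(!out$predicted[ok] & out$observed[ok])
  class(out) <- c("screen_report", class(out))
  attr(out, "confusion") <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  attr(out, "accuracy") <- if (sum(ok)) (tp + tn) / sum(ok) else NA_real_
  out
}

#' Oxygen-limitation thresholds from a robustness curve
#'
#' For each response column, the unconstrained value is the response at the
#' largest uptake bound; the threshold is the largest grid value at which
#' the response has dropped below 99 % of it.
#'
#' @param curve a `robustness_curve` from [robustness_scan()] over an O2
#'   uptake grid.
#' @param responses response column names (e.g. `objective_BIOMASS`).
#' @return named numeric vector of threshold bounds (NA when the response
#'   never drops).
#' @export
o2_thresholds <- function(curve, responses) {
  ord <- order(curve$bound)
  bound <- curve$bound[ord]
  vapply(responses, function(col) {
    y <- curve[[col]][ord]
    ref <- y[length(y)]
    below <- which(y < 0.99 * ref)
    if (!length(below)) return(NA_real_)
    bound[max(below)]
  }, numeric(1))
}
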