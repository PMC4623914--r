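# Variable-lipid biomass equations and the split maintenance-energy model.
#
# The biomass pseudo-reaction is parameterised by the neutral-lipid (TAG)
# mass fraction f of cell dry weight: TAG coefficients deliver f grams per
# gDW while every non-lipid component is rescaled by (1 - f)/(1 - f_ref),
# which reduces protein proportionally, keeps the relative amounts of the
# non-lipid components constant, and preserves the 1 g/gDW mass total.
# Maintenance ATP is split: growth-associated maintenance (GAM) is hydrolysed
# inside the biomass reaction, non-growth-associated maintenance (NGAM) is a
# separate ATP-hydrolysis flux coupled to substrate uptake with a fixed
# mmol-ATP-per-mmol-substrate ratio, so it persists when growth is zero.

#' Default fatty-acyl profile and molecular weights
#'
#' A four-species acyl profile (palmitate, palmitoleate, oleate, linoleate)
#' used when no experimentally determined phase-specific composition is
#' supplied; fractions are mole fractions and weights free-acid g/mol.
#'
#' @return named list with `profile` and `mw`.
#' @export
default_fa_profile <- function() {
  list(profile = c(C16_0 = 0.15, C16_1 = 0.10, C18_1 = 0.55, C18_2 = 0.20),
       mw = c(C16_0 = 256.42, C16_1 = 254.41, C18_1 = 282.46, C18_2 = 280.45))
}

#' Molar weight of the lumped TAG pseudo-species
#'
#' TAG is assembled from a glycerol backbone and three acyl chains drawn
#' from the profile, losing one water per ester bond.
#'
#' @param fa_profile named mole fractions summing to 1.
#' @param fa_mw named fatty-acid weights (g/mol) covering the profile.
#' @return TAG weight in g/mol.
#' @export
tag_weight <- function(fa_profile = default_fa_profile()$profile,
                       fa_mw = default_fa_profile()$mw) {
  if (abs(sum(fa_profile) - 1) > 1e-6)
    stop("fa_profile fractions must sum to 1")
  miss <- setdiff(names(fa_profile), names(fa_mw))
  if (length(miss)) stop("missing molecular weight for fatty acid: ", miss[1])
  92.09 + 3 * sum(fa_profile * fa_mw[names(fa_profile)]) - 3 * 18.02
}

#' Biomass specification with variable neutral-lipid content
#'
#' @param f_NL neutral-lipid mass fraction of dry weight, in [0.004, 0.80].
#' @param base_composition named mmol-per-gDW of the non-lipid components at
#'   the reference state (names are model metabolite ids).
#' @param component_mw named g/mol weights for the base components.
#' @param fa_profile,fa_mw acyl composition, see [tag_weight()].
#' @param GAM growth-associated maintenance, mmol ATP per gDW.
#' @param reference_f lipid fraction at which `base_composition` was
#'   measured (its mass must sum to `1 - reference_f` g within 0.5 %).
#' @param cofactors named signed stoichiometry (negative = consumed) for
#'   the redox/energy bookkeeping of biosynthesis, e.g. the net NADH
#'   released while building the non-lipid fraction; scaled with the
#'   non-lipid components and excluded from the mass balance.
#' @return object of class `biomass_spec`.
#' @export
biomass_spec <- function(f_NL, base_composition, component_mw,
                         fa_profile = default_fa_profile()$profile,
                         fa_mw = default_fa_profile()$mw,
                         GAM = 17.05, reference_f = 0.004,
                         cofactors = numeric()) {
  if (f_NL < 0.004 || f_NL > 0.80)
    stop("f_NL outside [0.004, 0.80]: ", f_NL)
  miss <- setdiff(names(base_composition), names(component_mw))
  if (length(miss)) stop("missing molecular weight for component: ", miss[1])
  if (abs(sum(fa_profile) - 1) > 1e-6)
    stop("fa_profile fractions must sum to 1")
  base_mass <- sum(base_composition *
                     component_mw[names(base_composition)] / 1000)
  if (abs(base_mass - (1 - reference_f)) > 0.005)
    stop(sprintf(paste0("base composition mass is %.4f g/gDW; expected ",
                        "%.4f (1 - reference_f) within 0.5 %%"),
                 base_mass, 1 - reference_f))
  structure(list(f_NL = f_NL, base_composition = base_composition,
                 component_mw = component_mw, fa_profile = fa_profile,
                 fa_mw = fa_mw, GAM = GAM, reference_f = reference_f,
                 cofactors = cofactors),
            class = "biomass_spec")
}

#' Build the biomass pseudo-reaction for a lipid fraction
#'
#' Returns an `add_reaction` directive: TAG drawn at `f_NL / MW_TAG`
#' mmol/gDW, non-lipid components rescaled by
#' `(1 - f_NL)/(1 - reference_f)`, and GAM ATP hydrolysis included. The
#' reaction is a drain (flux unit h^-1: one unit of flux polymerises 1 gDW
#' of biomass per gDW per hour).
#'
#' @param spec a [biomass_spec].
#' @param tag metabolite id of the TAG pseudo-species.
#' @param atp,adp metabolite ids for the GAM hydrolysis.
#' @param id reaction id of the biomass equation.
#' @return directive for [apply_edits()], with attribute `mass` (g/gDW).
#' @export
build_biomass <- function(spec, tag, atp, adp, id = "BIOMASS") {
  stopifnot(inherits(spec, "biomass_spec"))
  mw_tag <- tag_weight(spec$fa_profile, spec$fa_mw)
  scale <- (1 - spec$f_NL) / (1 - spec$reference_f)
  sto <- -spec$base_composition * scale
  names(sto) <- names(spec$base_composition)
  tag_coef <- spec$f_NL / (mw_tag / 1000)
  sto[tag] <- if (tag %in% names(sto)) sto[[tag]] - tag_coef else -tag_coef
  for (nm in names(spec$cofactors)) {
    add <- spec$cofactors[[nm]] * scale
    sto[nm] <- if (nm %in% names(sto)) sto[[nm]] + add else add
  }
  sto[atp] <- if (atp %in% names(sto)) sto[[atp]] - spec$GAM else -spec$GAM
  sto[adp] <- spec$GAM
  mass <- sum(spec$base_composition * scale *
                spec$component_mw[names(spec$base_composition)] / 1000) +
    spec$f_NL
  if (abs(mass - 1) > 0.005)
    stop(sprintf("biomass mass sums to %.4f g/gDW (must be 1 within 0.5 %%)",
                 mass))
  ed <- edit_add_reaction(id, stoichiometry = sto, lb = 0, ub = 1000,
                          name = sprintf("biomass (%.1f %% NL)",
                                         100 * spec$f_NL),
                          subsystem = "biomass", pseudo = TRUE)
  attr(ed, "mass") <- mass
  attr(ed, "spec") <- spec
  ed
}

#' Swap a model's biomass equation for a given lipid fraction
#'
#' Replaces the stoichiometry of the existing biomass reaction (objective
#' weight and bounds preserved) with the one built from `spec`.
#'
#' @param model a [metabolic_model].
#' @inheritParams build_biomass
#' @return the modified model.
#' @export
set_biomass <- function(model, spec, tag, atp, adp, id = "BIOMASS") {
  j <- match(id, model$reactions$id)
  if (is.na(j)) stop("no biomass reaction ", id, " in model")
  old <- model$reactions[j, ]
  ed <- build_biomass(spec, tag = tag, atp = atp, adp = adp, id = id)
  m <- apply_edits(model, list(edit_remove_reaction(id), ed))
  k <- match(id, m$reactions$id)
  m$reactions$objective[k] <- old$objective
  m$reactions$lb[k] <- old$lb
  m$reactions$ub[k] <- old$ub
  m
}

#' Rescale the lipid fraction of an existing biomass equation
#'
#' For models whose biomass composition comes from the model file rather
#' than a [biomass_spec]: the TAG coefficient is reset to deliver `f_NL`
#' grams per gDW (TAG weight from the species formula, or `tag_mw`), and
#' every other coefficient is rescaled by `(1 - f_NL)/(1 - f_ref)` where
#' `f_ref` is the current TAG mass fraction read off the equation.
#'
#' @param model a [metabolic_model].
#' @param f_NL target neutral-lipid fraction in [0.004, 0.80].
#' @param tag TAG metabolite id(s); the first one present is used.
#' @param id biomass reaction id.
#' @param tag_mw TAG molar weight (g/mol) override.
#' @return the modified model.
#' @export
rescale_biomass_lipid <- function(model, f_NL, tag, id = "BIOMASS",
                                  tag_mw = NULL) {
  if (f_NL < 0.004 || f_NL > 0.80)
    stop("f_NL outside [0.004, 0.80]: ", f_NL)
  j <- match(id, model$reactions$id)
  if (is.na(j)) stop("no biomass reaction ", id, " in model")
  ti <- match(tag, model$metabolites$id)
  ti <- ti[!is.na(ti)][1]
  if (is.na(ti)) stop("TAG species not in model: ", paste(tag, collapse = ", "))
  mw <- if (!is.null(tag_mw)) tag_mw else
    formula_weight(model$metabolites$formula[ti])
  if (is.na(mw)) stop("no molecular weight for TAG species ",
                      model$metabolites$id[ti], "; pass tag_mw")
  f_ref <- max(0, -model$S[ti, j]) * mw / 1000
  if (f_ref >= 1) stop("implausible reference lipid fraction: ", f_ref)
  scale <- (1 - f_NL) / (1 - f_ref)
  col <- model$S[, j] * scale
  col[ti] <- -f_NL / (mw / 1000)
  model$S[, j] <- col
  model
}

#' Split maintenance energy: GAM in biomass, NGAM coupled to uptake
#'
#' Ensures an ATP-hydrolysis pseudo-reaction exists and couples its flux to
#' the substrate uptake magnitude: `v[atpase] = ngam_ratio * uptake`. With
#' the package's negative-uptake convention this is the coupling row
#' `v[atpase] + ngam_ratio * v[substrate] = 0`. Optionally resets the GAM
#' ATP/ADP coefficients of a biomass reaction built by [build_biomass()].
#'
#' @param model a [metabolic_model].
#' @param ngam_ratio mmol ATP per mmol substrate taken up (glucose 5.0,
#'   glycerol 2.28 in the reference parameterisation).
#' @param substrate substrate exchange reaction id.
#' @param atp,adp metabolite ids for the hydrolysis reaction.
#' @param atpase id of the ATP-maintenance reaction (created when absent).
#' @param gam optional new GAM (mmol/gDW) written into the biomass reaction
#'   `biomass_id` (its previous ATP/ADP coefficients are assumed to be GAM
#'   only, as produced by [build_biomass()]).
#' @param biomass_id biomass reaction id used when `gam` is given.
#' @return the modified model.
#' @export
set_maintenance <- function(model, ngam_ratio, substrate, atp, adp,
                            atpase = "ATPM", gam = NULL,
                            biomass_id = "BIOMASS") {
  stopifnot(ngam_ratio >= 0)
  if (!substrate %in% model$reactions$id)
    stop("unknown substrate exchange: ", substrate)
  if (!atpase %in% model$reactions$id) {
    sto <- setNames(c(-1, 1), c(atp, adp))
    model <- apply_edits(model, edit_add_reaction(
      atpase, stoichiometry = sto, lb = 0, ub = 1000,
      name = "ATP maintenance requirement", subsystem = "maintenance",
      pseudo = TRUE))
  }
  model$couplings <- model$couplings[model$couplings$target != atpase, ,
                                     drop = FALSE]
  # uptake flux is negative, so ratio enters with opposite sign
  model <- couple_fluxes(model, atpase, substrate, -ngam_ratio)
  if (!is.null(gam)) {
    j <- match(biomass_id, model$reactions$id)
    if (is.na(j)) stop("no biomass reaction ", biomass_id, " in model")
    ai <- match(c(atp, adp), model$metabolites$id)
    if (anyNA(ai)) stop("atp/adp metabolite not in model")
    model$S[ai[1], j] <- -gam
    model$S[ai[2], j] <- gam
  }
  model
}
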