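# Synthetic core model: a compartmentalized, carbon-balanced caricature of
# oleaginous-yeast central metabolism small enough that every FBA optimum
# can be recomputed by exhaustive vertex enumeration. Lumped pathway
# segments: glycolysis (glucose -> 2 pyruvate + ATP + NADH), an oxidative
# PPP cycle (glucose -> 6 CO2 + NADPH), citrate synthesis from glucose,
# ATP:citrate lyase feeding acetyl-CoA to fatty-acid synthesis (2 NADPH per
# C2 unit), TAG assembly, full pyruvate oxidation, oxidative phosphorylation
# with a tunable P/O ratio, citrate/pyruvate exporters, a variable-lipid
# biomass drain and an NGAM ATP hydrolysis coupled to glucose uptake.
# Stoichiometry is deterministic; a seed only permutes identifiers.

#' Specification of the synthetic core model
#'
#' @param include_ppp oxidative PPP as NADPH source.
#' @param include_citrate citrate exporter (overflow route).
#' @param include_lipid ATP:citrate lyase, fatty-acid/TAG synthesis and the
#'   TAG demand (requires a NADPH source: PPP or transhydrogenase).
#' @param include_o2 respiratory chain and O2 exchange.
#' @param include_ngam NGAM ATP hydrolysis coupled to glucose uptake.
#' @param include_thd energy-independent NADH -> NADPH transhydrogenase.
#' @param include_idh cytosolic NADP-dependent isocitrate dehydrogenase
#'   route (citrate -> 2-oxoglutarate + CO2 + NADPH).
#' @param include_pyr_export pyruvate exporter (anaerobic overflow).
#' @param po_ratio ATP per NADH oxidised (P/O), default 2.
#' @param glyc_atp net ATP per glucose through glycolysis, default 2.
#' @param ppp_nadph NADPH per glucose through the cyclic PPP, default 12.
#' @param glc_uptake default glucose uptake bound, mmol/gDW/h.
#' @param ngam_ratio mmol ATP maintenance per mmol glucose taken up.
#' @param gam growth-associated maintenance, mmol ATP/gDW.
#' @param f_NL neutral-lipid fraction of the default biomass equation.
#' @param seed permutes metabolite/reaction order (ids unchanged); `NULL`
#'   keeps canonical order.
#' @return list of class `toy_model_spec`.
#' @export
toy_model_spec <- function(include_ppp = TRUE, include_citrate = TRUE,
                           include_lipid = TRUE, include_o2 = TRUE,
                           include_ngam = TRUE, include_thd = FALSE,
                           include_idh = FALSE, include_pyr_export = FALSE,
                           po_ratio = 2, glyc_atp = 2, ppp_nadph = 12,
                           glc_uptake = 10, ngam_ratio = 1, gam = 17.05,
                           f_NL = 0.05, seed = NULL) {
  spec <- as.list(environment())
  if (spec$include_lipid && !(spec$include_ppp || spec$include_thd))
    stop("lipid synthesis needs a NADPH source: enable PPP or THD")
  stopifnot(po_ratio > 0, glyc_atp >= 0, ppp_nadph > 0, glc_uptake > 0,
            ngam_ratio >= 0, gam >= 0)
  class(spec) <- "toy_model_spec"
  spec
}

# pyruvate stands in for the whole non-lipid biomass fraction
.TOY_PYR_MW <- 88.062   # g/mol, from C3H4O3

#' Reference biomass specification for the synthetic model
#'
#' Non-lipid biomass is lumped into a pyruvate drain; TAG is tripalmitin
#' (single-species acyl profile).
#'
#' @param f_NL lipid fraction.
#' @param gam growth-associated maintenance, mmol ATP/gDW.
#' @param reference_f reference lipid fraction of the non-lipid block.
#' @return a [biomass_spec].
#' @export
toy_biomass_spec <- function(f_NL = 0.05, gam = 17.05,
                             reference_f = 0.004) {
  biomass_spec(
    f_NL = f_NL,
    base_composition = c(pyr_c = 1000 * (1 - reference_f) / .TOY_PYR_MW),
    component_mw = c(pyr_c = .TOY_PYR_MW),
    fa_profile = c(C16_0 = 1),
    fa_mw = c(C16_0 = 256.42),
    GAM = gam, reference_f = reference_f,
    # biosynthesis of the non-lipid fraction net-releases reducing
    # equivalents (the respiratory quotient of growth exceeds 1), which
    # is what makes growth more oxygen-hungry than storage-lipid synthesis
    cofactors = c(nad_c = -16, nadh_c = 16))
}

.toy_metabolites <- function(spec) {
  m <- list(
    c("glc_e", "D-glucose", "e", "C6H12O6"),
    c("glc_c", "D-glucose", "c", "C6H12O6"),
    c("pyr_c", "pyruvate", "c", "C3H4O3"),
    c("co2_c", "carbon dioxide", "c", "CO2"),
    c("co2_e", "carbon dioxide", "e", "CO2"),
    c("nad_c", "NAD+", "c", "C21H27N7O14P2"),
    c("nadh_c", "NADH", "c", "C21H28N7O14P2"),
    c("atp_c", "ATP", "c", "C10H16N5O13P3"),
    c("adp_c", "ADP", "c", "C10H15N5O10P2"))
  if (spec$include_o2) m <- c(m, list(
    c("o2_e", "oxygen", "e", "O2"),
    c("o2_c", "oxygen", "c", "O2")))
  if (spec$include_ppp || spec$include_lipid || spec$include_thd ||
      spec$include_idh) m <- c(m, list(
    c("nadp_c", "NADP+", "c", "C21H28N7O17P3"),
    c("nadph_c", "NADPH", "c", "C21H29N7O17P3")))
  if (spec$include_citrate || spec$include_lipid || spec$include_idh)
    m <- c(m, list(c("cit_c", "citrate", "c", "C6H8O7")))
  if (spec$include_citrate) m <- c(m, list(
    c("cit_e", "citrate", "e", "C6H8O7")))
  if (spec$include_lipid) m <- c(m, list(
    c("oaa_c", "oxaloacetate", "c", "C4H4O5"),
    c("accoa_c", "acetyl-CoA", "c", "C23H38N7O17P3S"),
    c("coa_c", "coenzyme A", "c", "C21H36N7O16P3S"),
    c("fa_c", "palmitate", "c", "C16H32O2"),
    c("tag_c", "triacylglycerol", "c", "C51H98O6")))
  if (spec$include_idh) m <- c(m, list(
    c("akg_c", "2-oxoglutarate", "c", "C5H6O5")))
  if (spec$include_pyr_export) m <- c(m, list(
    c("pyr_e", "pyruvate", "e", "C3H4O3")))
  df <- as.data.frame(do.call(rbind, m), stringsAsFactors = FALSE)
  names(df) <- c("id", "name", "compartment", "formula")
  df$charge <- NA_integer_
  df$boundary <- FALSE
  df
}

.toy_reactions <- function(spec) {
  rx <- list()
  add <- function(id, sto, lb = 0, ub = 1000, name = id, sub = "",
                  pseudo = FALSE, obj = 0, gpr = "") {
    rx[[length(rx) + 1L]] <<- list(id = id, sto = sto, lb = lb, ub = ub,
                                   name = name, sub = sub, pseudo = pseudo,
                                   obj = obj, gpr = gpr)
  }
  add("EX_glc", c(glc_e = -1), lb = -spec$glc_uptake,
      name = "glucose exchange", sub = "exchange")
  add("GLCt", c(glc_e = -1, glc_c = 1), name = "glucose transport",
      sub = "transport", gpr = "YL_HXT1")
  # redox-neutral glycolytic lump: the NADH bookkeeping of the pathway is
  # folded into the downstream TCA/citrate lumps so the network remains
  # operable when oxygen is closed (fermentative pyruvate overflow)
  add("GLYC", c(glc_c = -1, adp_c = -spec$glyc_atp,
                pyr_c = 2, atp_c = spec$glyc_atp),
      name = "glycolysis (lumped)", sub = "glycolysis",
      gpr = "YL_GLK1 and YL_PYK1")
  add("PYRTCA", c(pyr_c = -1, nad_c = -6, co2_c = 3, nadh_c = 6),
      name = "pyruvate oxidation via TCA (lumped)", sub = "tca")
  if (spec$include_o2) {
    add("OXPHOS", c(o2_c = -1, nadh_c = -2, adp_c = -2 * spec$po_ratio,
                    nad_c = 2, atp_c = 2 * spec$po_ratio),
        name = "oxidative phosphorylation", sub = "oxphos",
        gpr = "YL_NDH1 or YL_NDH2")
    # non-phosphorylating alternative oxidase: lets the cell reoxidise
    # NADH without forcing ATP synthesis (Y. lipolytica has AOX), so the
    # respiratory ATP yield is an upper bound, not an equality
    add("AOX", c(o2_c = -1, nadh_c = -2, nad_c = 2),
        name = "alternative oxidase (non-phosphorylating)", sub = "oxphos")
    add("O2t", c(o2_e = -1, o2_c = 1), name = "oxygen transport",
        sub = "transport")
    add("EX_o2", c(o2_e = -1), lb = -1000, name = "oxygen exchange",
        sub = "exchange")
  }
  add("CO2t", c(co2_c = -1, co2_e = 1), name = "CO2 transport",
      sub = "transport")
  add("EX_co2", c(co2_e = -1), lb = -1000, name = "CO2 exchange",
      sub = "exchange")
  if (spec$include_ppp)
    add("PPP", c(glc_c = -1, nadp_c = -spec$ppp_nadph, co2_c = 6,
                 nadph_c = spec$ppp_nadph),
        name = "oxidative pentose phosphate cycle (lumped)", sub = "ppp",
        gpr = "YL_ZWF1")
  if (spec$include_citrate || spec$include_lipid || spec$include_idh)
    add("CITSYN", c(glc_c = -1, adp_c = -2, nad_c = -3,
                    cit_c = 1, atp_c = 2, nadh_c = 3),
        name = "citrate synthesis from glucose (lumped)", sub = "tca")
  if (spec$include_citrate) {
    add("CITt", c(cit_c = -1, cit_e = 1), name = "citrate export",
        sub = "transport")
    add("EX_cit", c(cit_e = -1), name = "citrate exchange",
        sub = "exchange")
  }
  if (spec$include_lipid) {
    add("ACL", c(cit_c = -1, atp_c = -1, coa_c = -1,
                 oaa_c = 1, accoa_c = 1, adp_c = 1),
        name = "ATP:citrate lyase", sub = "lipid")
    add("OAADC", c(oaa_c = -1, pyr_c = 1, co2_c = 1),
        name = "oxaloacetate recycling (lumped)", sub = "tca")
    add("FAS", c(accoa_c = -8, nadph_c = -14, atp_c = -7,
                 fa_c = 1, coa_c = 8, nadp_c = 14, adp_c = 7),
        name = "fatty-acid synthesis (C16, lumped)", sub = "lipid",
        gpr = "YL_FAS1 and YL_FAS2")
    add("TAGS", c(fa_c = -3, glc_c = -0.5, atp_c = -1,
                  tag_c = 1, adp_c = 1),
        name = "TAG assembly", sub = "lipid")
    add("DM_tag", c(tag_c = -1), name = "TAG demand", sub = "lipid",
        pseudo = TRUE)
  }
  if (spec$include_idh) {
    add("IDHy", c(cit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1,
                  nadph_c = 1),
        name = "cytosolic NADP isocitrate dehydrogenase (lumped)",
        sub = "tca")
    add("AKGOX", c(akg_c = -1, nad_c = -2, pyr_c = 1, co2_c = 2,
                   nadh_c = 2),
        name = "2-oxoglutarate re-entry (lumped)", sub = "tca")
  }
  if (spec$include_thd)
    add("THD", c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
        name = "energy-independent transhydrogenase", sub = "redox")
  if (spec$include_pyr_export) {
    add("PYRt", c(pyr_c = -1, pyr_e = 1), name = "pyruvate export",
        sub = "transport")
    add("EX_pyr", c(pyr_e = -1), name = "pyruvate exchange",
        sub = "exchange")
  }
  # ATP-maintenance hydrolysis: always present as the energy drain (its
  # coupling to substrate uptake is controlled by include_ngam)
  add("ATPM", c(atp_c = -1, adp_c = 1),
      name = "ATP maintenance requirement", sub = "maintenance",
      pseudo = TRUE)
  # futile ATP cycling: genome-scale networks can always dissipate surplus
  # ATP through substrate cycles; the lumped toy needs the valve explicitly,
  # since the NGAM coupling pins ATPM itself to the uptake rate
  add("FUTILE", c(atp_c = -1, adp_c = 1),
      name = "futile ATP cycling (lumped)", sub = "maintenance",
      pseudo = TRUE)
  rx
}

#' Build the synthetic core model
#'
#' @param spec a [toy_model_spec].
#' @param manifest also compute the generation manifest, including the
#'   enumeration-oracle optimum of the default objective.
#' @return a [metabolic_model]; when `manifest = TRUE` the manifest is in
#'   `attr(model, "manifest")`.
#' @export
build_toy_model <- function(spec = toy_model_spec(), manifest = TRUE) {
  stopifnot(inherits(spec, "toy_model_spec"))
  met <- .toy_metabolites(spec)
  rxl <- .toy_reactions(spec)
  rxn <- data.frame(
    id = vapply(rxl, `[[`, character(1), "id"),
    name = vapply(rxl, `[[`, character(1), "name"),
    lb = vapply(rxl, `[[`, numeric(1), "lb"),
    ub = vapply(rxl, `[[`, numeric(1), "ub"),
    gene_rule = vapply(rxl, `[[`, character(1), "gpr"),
    subsystem = vapply(rxl, `[[`, character(1), "sub"),
    objective = vapply(rxl, `[[`, numeric(1), "obj"),
    pseudo = vapply(rxl, `[[`, logical(1), "pseudo"),
    stringsAsFactors = FALSE)
  S <- matrix(0, nrow(met), nrow(rxn),
              dimnames = list(met$id, rxn$id))
  for (j in seq_along(rxl))
    S[names(rxl[[j]]$sto), j] <- rxl[[j]]$sto
  compartments <- data.frame(
    id = c("c", "e"), name = c("cytosol", "extracellular"),
    outside = c("e", NA), stringsAsFactors = FALSE)
  if (!is.null(spec$seed)) {
    # permute identifiers without touching the caller's RNG stream
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(spec$seed)
    mp <- sample(nrow(met)); rp <- sample(nrow(rxn))
    met <- met[mp, , drop = FALSE]
    rxn <- rxn[rp, , drop = FALSE]
    S <- S[mp, rp, drop = FALSE]
  }
  model <- metabolic_model("toy_oleaginous_core", met, rxn, S,
                           compartments, external = "e")
  # biomass with the lipid fraction (TAG term only when lipid is modelled)
  if (spec$include_lipid) {
    bspec <- toy_biomass_spec(f_NL = spec$f_NL, gam = spec$gam)
    ed <- build_biomass(bspec, tag = "tag_c", atp = "atp_c", adp = "adp_c")
  } else {
    # lipid-free variant: no biosynthetic NADH term, so the reduced
    # (anaerobic-capable) models keep a nonzero growth optimum
    sto <- c(pyr_c = -1000 * (1 - 0.004) / .TOY_PYR_MW,
             atp_c = -spec$gam, adp_c = spec$gam)
    ed <- edit_add_reaction("BIOMASS", stoichiometry = sto, lb = 0,
                            ub = 1000, name = "biomass (lipid-free)",
                            subsystem = "biomass", pseudo = TRUE)
  }
  model <- apply_edits(model, list(ed, edit_set_objective(c(BIOMASS = 1))))
  if (spec$include_ngam)
    model <- set_maintenance(model, ngam_ratio = spec$ngam_ratio,
                             substrate = "EX_glc", atp = "atp_c",
                             adp = "adp_c")
  attr(model, "toy_spec") <- spec
  if (manifest) attr(model, "manifest") <- .toy_manifest(model, spec)
  model
}

# manifest: what was emitted plus oracle-computed optima (never typed in)
.toy_manifest <- function(model, spec) {
  kinds <- reaction_kinds(model)
  man <- list(
    spec = unclass(spec),
    n_reactions = nrow(model$reactions),
    n_metabolites = nrow(model$metabolites),
    n_exchange = sum(kinds == "exchange"),
    n_transport = sum(kinds == "transport"),
    n_enzymatic = sum(kinds == "enzymatic"),
    n_pseudo = sum(kinds == "pseudo"),
    reactions = model$reactions$id)
  man$expected_max_growth <- tryCatch(
    fba_by_enumeration(model, "BIOMASS", "max")$objective_value,
    error = function(e) NA_real_)
  if (spec$include_lipid) {
    m0 <- apply_edits(model, list(
      edit_set_bounds("BIOMASS", lb = 0, ub = 0)))
    man$expected_max_lipid_growth0 <- tryCatch(
      fba_by_enumeration(m0, "DM_tag", "max")$objective_value,
      error = function(e) NA_real_)
  }
  man
}

#' Four-substrate growth-screen fixture
#'
#' A reduced synthetic model extended with fructose and mannose assimilation
#' and a dead-end sucrose exchange (no invertase), plus a truth table with
#' one planted false positive (mannose: the network grows, the organism
#' does not), so the expected confusion matrix is TP=2, FP=1, TN=1,
#' accuracy 0.75.
#'
#' @return list with `model`, `substrates`, `truth` and `free_exchanges`.
#' @export
toy_screen_fixture <- function() {
  spec <- toy_model_spec(include_ppp = FALSE, include_citrate = FALSE,
                         include_lipid = FALSE, include_ngam = FALSE)
  model <- build_toy_model(spec, manifest = FALSE)
  ed <- list(
    edit_add_metabolite("fru_e", "D-fructose", "e", "C6H12O6"),
    edit_add_metabolite("fru_c", "D-fructose", "c", "C6H12O6"),
    edit_add_metabolite("man_e", "D-mannose", "e", "C6H12O6"),
    edit_add_metabolite("man_c", "D-mannose", "c", "C6H12O6"),
    edit_add_metabolite("sucr_e", "sucrose", "e", "C12H22O11"),
    edit_add_reaction("EX_fru", c(fru_e = -1), lb = 0, ub = 1000,
                      name = "fructose exchange", subsystem = "exchange"),
    edit_add_reaction("FRUt", c(fru_e = -1, fru_c = 1), lb = 0,
                      name = "fructose transport", subsystem = "transport"),
    edit_add_reaction("FRUI", c(fru_c = -1, glc_c = 1), lb = 0,
                      name = "fructose isomerisation", subsystem = "sugar"),
    edit_add_reaction("EX_man", c(man_e = -1), lb = 0, ub = 1000,
                      name = "mannose exchange", subsystem = "exchange"),
    edit_add_reaction("MANt", c(man_e = -1, man_c = 1), lb = 0,
                      name = "mannose transport", subsystem = "transport"),
    edit_add_reaction("MANI", c(man_c = -1, glc_c = 1), lb = 0,
                      name = "mannose isomerisation", subsystem = "sugar"),
    edit_add_reaction("EX_sucr", c(sucr_e = -1), lb = 0, ub = 1000,
                      name = "sucrose exchange (no invertase)",
                      subsystem = "exchange"))
  model <- apply_edits(model, ed)
  list(model = model,
       substrates = c("EX_glc", "EX_fru", "EX_man", "EX_sucr"),
       truth = c(EX_glc = TRUE, EX_fru = TRUE, EX_man = FALSE,
                 EX_sucr = FALSE),
       free_exchanges = c("EX_o2", "EX_co2"))
}
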