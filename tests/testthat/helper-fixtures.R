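# Shared fixtures: tiny hand-built models and the battery of toy-model
# configurations used by the oracle-agreement property tests.

# two-metabolite, three-reaction chain: A_e -> A_c -> (drain), with an
# exchange supplying A_e; optimum is the uptake bound
chain_model <- function(uptake = 5) {
  met <- data.frame(id = c("A_e", "A_c"),
                    name = c("A", "A"),
                    compartment = c("e", "c"),
                    formula = c("C1", "C1"),
                    charge = NA_integer_, boundary = FALSE,
                    stringsAsFactors = FALSE)
  rxn <- data.frame(id = c("EX_A", "At", "DM_A"),
                    name = c("A exchange", "A transport", "A demand"),
                    lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000),
                    gene_rule = c("", "gA", ""),
                    subsystem = "", objective = c(0, 0, 1),
                    pseudo = c(FALSE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  S <- matrix(c(-1, 0,
                -1, 1,
                0, -1), nrow = 2,
              dimnames = list(met$id, rxn$id))
  comp <- data.frame(id = c("c", "e"), name = c("cytosol", "external"),
                     outside = c("e", NA), stringsAsFactors = FALSE)
  metabolic_model("chain", met, rxn, S, comp, external = "e")
}

# toy-model configurations for oracle-agreement loops: small enough that
# exhaustive vertex enumeration stays fast, varied in topology and in the
# stoichiometric parameters (P/O ratio, glycolytic ATP, PPP NADPH yield,
# NGAM ratio)
oracle_specs <- function() {
  specs <- list()
  push <- function(...) specs[[length(specs) + 1L]] <<- toy_model_spec(...)
  # minimal respiratory models across P/O, glycolytic ATP and NGAM (16)
  for (po in c(1, 1.5, 2, 2.5))
    for (ga in c(1, 2))
      for (ng in c(0, 1))
        push(include_ppp = FALSE, include_citrate = FALSE,
             include_lipid = FALSE, po_ratio = po, glyc_atp = ga,
             ngam_ratio = ng)
  # anaerobic (no respiratory chain) variants (4)
  for (ga in c(1, 2))
    for (up in c(2, 6))
      push(include_ppp = FALSE, include_citrate = FALSE,
           include_lipid = FALSE, include_o2 = FALSE, glyc_atp = ga,
           glc_uptake = up)
  # citrate-overflow models (6)
  for (po in c(1, 2, 2.5))
    for (ng in c(0, 1))
      push(include_ppp = FALSE, include_citrate = TRUE,
           include_lipid = FALSE, po_ratio = po, ngam_ratio = ng)
  # PPP-carrying models (4)
  for (nad in c(6, 12))
    for (po in c(1, 2))
      push(include_citrate = FALSE, include_lipid = FALSE,
           ppp_nadph = nad, po_ratio = po)
  # identifier permutations of small topologies (8)
  for (seed in 1:4)
    push(include_ppp = FALSE, include_citrate = FALSE,
         include_lipid = FALSE, seed = seed)
  for (seed in 5:8)
    push(include_ppp = TRUE, include_citrate = TRUE,
         include_lipid = FALSE, seed = seed)
  # PPP + citrate overflow (4)
  for (po in c(1, 1.5, 2, 2.5))
    push(include_citrate = TRUE, include_lipid = FALSE, po_ratio = po)
  # transhydrogenase-carrying models (2)
  for (po in c(1, 2))
    push(include_ppp = FALSE, include_citrate = FALSE,
         include_lipid = FALSE, include_thd = TRUE, po_ratio = po)
  # full lipid-synthesis models, without and with citrate export (6 + 2)
  for (po in c(1, 2))
    for (f in c(0.05, 0.3, 0.6))
      push(include_citrate = FALSE, include_lipid = TRUE,
           po_ratio = po, f_NL = f)
  for (po in c(1.5, 2))
    push(include_citrate = TRUE, include_lipid = TRUE, po_ratio = po)
  specs
}

# total carbon drained per unit flux of a reaction (positive = consumed)
reaction_carbon_drain <- function(model, reaction) {
  j <- match(reaction, model$reactions$id)
  part <- which(model$S[, j] != 0)
  carb <- vapply(model$metabolites$formula[part], function(f) {
    ct <- parse_formula(f)
    if ("C" %in% names(ct)) ct[["C"]] else 0
  }, numeric(1))
  -sum(model$S[part, j] * carb)
}
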