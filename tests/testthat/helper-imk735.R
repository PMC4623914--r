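# Locator and scenario helpers for the iMK735 genome-scale model of
# Yarrowia lipolytica (BioModels MODEL1510060001, distributed as the
# study's supplementary SBML). The file is too large to bundle; point the
# package at a local copy via options(oleoflux.imk735 = "<path>") or the
# OLEOFLUX_IMK735 environment variable.

imk735_path <- function() {
  p <- getOption("oleoflux.imk735", Sys.getenv("OLEOFLUX_IMK735", ""))
  if (is.character(p) && length(p) == 1 && nzchar(p) && file.exists(p))
    p else NA_character_
}

imk735_missing_msg <- paste(
  "iMK735 SBML not available: supply the supplementary genome-scale model",
  "(BioModels MODEL1510060001) via options(oleoflux.imk735=...) or",
  "OLEOFLUX_IMK735; it cannot be bundled with the package")

# in-silico minimal medium: free uptake of inorganic/auxiliary species, all
# other exchanges closed for uptake (iND750-style exchange identifiers)
imk735_free_patterns <- c("^EX_co2", "^EX_h2o", "^EX_h\\b", "^EX_h\\(",
                          "^EX_h_", "^EX_inost", "^EX_k\\(", "^EX_k_",
                          "^EX_nh4", "^EX_na1", "^EX_o2", "^EX_pi",
                          "^EX_so4")

apply_imm <- function(model) {
  kinds <- reaction_kinds(model)
  ex <- model$reactions$id[kinds == "exchange"]
  free <- ex[Reduce(`|`, lapply(imk735_free_patterns, grepl, x = ex))]
  close_uptakes(model, keep_open = free)
}

imk735_find <- function(model, pattern) {
  hit <- grep(pattern, model$reactions$id, value = TRUE,
              ignore.case = TRUE)
  if (length(hit)) hit[1] else NA_character_
}

# additions needed for the NADPH-source comparison: a cytosolic malic
# enzyme, the two reactions completing the mannitol cycle, and an
# energy-independent transhydrogenase; metabolite ids resolved by pattern
imk735_nadph_edits <- function(model) {
  met <- function(p) {
    hit <- grep(p, model$metabolites$id, value = TRUE, ignore.case = TRUE)
    if (length(hit)) hit[1] else NA_character_
  }
  need <- c(mal = "^mal_L\\b|^mal\\b|^mal_L\\(c\\)|^mal_L\\[c\\]",
            pyr = "^pyr\\b|^pyr\\[c\\]|^pyr\\(c\\)",
            co2 = "^co2\\b|^co2\\[c\\]",
            nadp = "^nadp\\b|^nadp\\[c\\]",
            nadph = "^nadph\\b|^nadph\\[c\\]",
            nad = "^nad\\b|^nad\\[c\\]",
            nadh = "^nadh\\b|^nadh\\[c\\]",
            f6p = "^f6p\\b|^f6p\\[c\\]",
            m1p = "^mnl1p|mannitol 1-phosphate",
            mnl = "^mnl\\b|^mnl\\[c\\]|mannitol",
            fru = "^fru\\b|^fru\\[c\\]",
            h2o = "^h2o\\b|^h2o\\[c\\]",
            pi = "^pi\\b|^pi\\[c\\]",
            h = "^h\\b|^h\\[c\\]")
  ids <- vapply(need, met, character(1))
  ed <- list()
  if (!anyNA(ids[c("mal", "pyr", "co2", "nadp", "nadph")]))
    ed <- c(ed, list(edit_add_reaction(
      "MAE_cyt", setNames(c(-1, -1, 1, 1, 1),
                          ids[c("mal", "nadp", "pyr", "co2", "nadph")]),
      lb = 0, ub = 1000, name = "malic enzyme (NADP), cytosolic")))
  if (!anyNA(ids[c("m1p", "h2o", "mnl", "pi")]))
    ed <- c(ed, list(edit_add_reaction(
      "M1PP", setNames(c(-1, -1, 1, 1),
                       ids[c("m1p", "h2o", "mnl", "pi")]),
      lb = 0, ub = 1000, name = "mannitol-1-phosphatase")))
  if (!anyNA(ids[c("mnl", "nadp", "h", "fru", "nadph")]))
    ed <- c(ed, list(edit_add_reaction(
      "MNLDH", setNames(c(-1, -1, -1, 1, 1),
                        ids[c("mnl", "nadp", "h", "fru", "nadph")]),
      lb = -1000, ub = 1000, name = "mannitol 2-dehydrogenase (NADP)")))
  if (!anyNA(ids[c("nadh", "nadp", "nad", "nadph")]))
    ed <- c(ed, list(edit_add_reaction(
      "THD2", setNames(c(-1, -1, 1, 1),
                       ids[c("nadh", "nadp", "nad", "nadph")]),
      lb = 0, ub = 1000,
      name = "transhydrogenase (energy-independent)")))
  ed
}

# NADPH source reaction sets from the bundled pattern file (the added
# reactions MAE_cyt / MNLDH / M1PP / THD2 match its patterns)
imk735_nadph_sources <- function(model) {
  src <- nadph_source_sets(model)
  src[vapply(src, length, integer(1)) > 0]
}

imk735_map <- function(model) {
  resolve_map(scenario_map(
    growth = imk735_find(model, "biomass"),
    lipid = imk735_find(model, "^DM_.*tag|^DM_.*triglyc|triglyc.*demand"),
    glucose = imk735_find(model, "^EX_glc"),
    o2 = imk735_find(model, "^EX_o2"),
    co2 = imk735_find(model, "^EX_co2"),
    citrate = imk735_find(model, "^EX_cit"),
    pyruvate = imk735_find(model, "^EX_pyr"),
    acl = imk735_find(model, "^ACITL|citrate lyase|^ACL"),
    ppp = imk735_find(model, "^G6PDH|glucose 6-phosphate dehydrogenase"),
    atpase = imk735_find(model, "^ATPM"),
    nadph = "~nadph",
    accoa = "~accoa",
    atp = "~^atp",
    adp = "~^adp",
    tag = "~^triglyc|^tag"), model)
}
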