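# SBML round trips, model summaries, and declarative edits.

test_that("hand-written minimal SBML yields a 2x1 stoichiometric matrix", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="mini">',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="a" name="a" compartment="c"/>',
    '<species id="b" name="b" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions><reaction id="R1" reversible="true">',
    '<listOfReactants><speciesReference species="a" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b" stoichiometry="1"/></listOfProducts>',
    '</reaction></listOfReactions>',
    '</model></sbml>'), f)
  expect_message(m <- read_sbml(f), "defaulted bounds")
  expect_equal(dim(m$S), c(2L, 1L))
  expect_equal(as.numeric(m$S[, 1]), c(-1, 1))
  expect_equal(m$reactions$lb, -1000)  # reversible default
  expect_equal(m$reactions$ub, 1000)
})

test_that("write/read round trip preserves S, bounds, objective, GPRs", {
  m <- build_toy_model(toy_model_spec(include_thd = TRUE,
                                      include_pyr_export = TRUE),
                       manifest = FALSE)
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  idx <- match(m$reactions$id, m2$reactions$id)
  expect_false(anyNA(idx))
  expect_identical(m2$reactions$lb[idx], m$reactions$lb)
  expect_identical(m2$reactions$ub[idx], m$reactions$ub)
  expect_identical(m2$reactions$objective[idx], m$reactions$objective)
  expect_identical(m2$reactions$gene_rule[idx], m$reactions$gene_rule)
  expect_identical(m2$reactions$pseudo[idx], m$reactions$pseudo)
  midx <- match(m$metabolites$id, m2$metabolites$id)
  expect_identical(m2$metabolites$formula[midx], m$metabolites$formula)
  expect_equal(as.matrix(m2$S)[m$metabolites$id, m$reactions$id],
               as.matrix(m$S), ignore_attr = TRUE)
  # and the round trip composes to the identity once more
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("parse failures name the offending element", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model id='x'></model></sbml>", f)
  expect_error(read_sbml(f), "no compartments")
  expect_error(read_sbml(tempfile()), "no such file")
})

test_that("summary counts are consistent and reordering-invariant", {
  m <- build_toy_model(manifest = FALSE)
  s <- summarize_model(m)
  expect_equal(s$n_exchange + s$n_transport + s$n_enzymatic_with_gpr +
                 s$n_enzymatic_without_gpr + s$n_pseudo, s$n_reactions)
  # a seed permutes the tables; counts must not change
  m2 <- build_toy_model(toy_model_spec(seed = 99), manifest = FALSE)
  s2 <- summarize_model(m2)
  expect_equal(unclass(s2), unclass(s))
  # toy generator manifest records what it emitted
  m3 <- build_toy_model()
  man <- attr(m3, "manifest")
  s3 <- summarize_model(m3)
  expect_equal(s3$n_exchange, man$n_exchange)
  expect_equal(s3$n_transport, man$n_transport)
  expect_equal(s3$n_pseudo, man$n_pseudo)
})

test_that("apply_edits returns a new model and the identity on empty edits", {
  m <- build_toy_model(manifest = FALSE)
  snapshot <- m
  m2 <- apply_edits(m, list())
  expect_equal(m2$reactions, m$reactions)
  expect_equal(as.matrix(m2$S), as.matrix(m$S))
  # a real edit leaves the input untouched
  m3 <- apply_edits(m, edit_set_bounds("EX_glc", lb = 0))
  expect_equal(m, snapshot)
  expect_equal(m3$reactions$lb[m3$reactions$id == "EX_glc"], 0)
})

test_that("reversible NADP-dehydrogenase addition carries its four participants", {
  # mannitol-cycle-style completion: new species plus a reversible
  # NADP-linked dehydrogenase, checked for carbon balance
  m <- build_toy_model(manifest = FALSE)
  ed <- list(
    edit_add_metabolite("mnl_c", "mannitol", "c", "C6H14O6"),
    edit_add_metabolite("fru_c", "D-fructose", "c", "C6H12O6"),
    edit_add_reaction("MNLDH",
                      c(mnl_c = -1, nadp_c = -1, fru_c = 1, nadph_c = 1),
                      lb = -1000, ub = 1000,
                      name = "mannitol dehydrogenase (NADP)"))
  m2 <- apply_edits(m, ed)
  j <- match("MNLDH", m2$reactions$id)
  expect_equal(sum(m2$S[, j] != 0), 4)
  expect_equal(m2$reactions$lb[j], -1000)  # reversible
  imb <- reaction_imbalance(m2, "MNLDH", "C")
  expect_equal(unname(imb["C"]), 0)
})

test_that("unbalanced enzymatic additions are rejected with the imbalance", {
  m <- build_toy_model(manifest = FALSE)
  bad <- edit_add_reaction("BAD", c(glc_c = -1, pyr_c = 1))  # C6 -> C3
  expect_error(apply_edits(m, bad), "unbalanced.*C \\-3")
  expect_silent(apply_edits(m, bad, balance = "none"))
})

test_that("closing an exporter removes excretion but keeps growth feasible", {
  m <- build_toy_model(manifest = FALSE)
  m2 <- apply_edits(m, edit_set_bounds("EX_cit", lb = 0, ub = 0))
  sol <- solve_fba(m2, "BIOMASS", "max")
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
  expect_equal(unname(sol$fluxes[["EX_cit"]]), 0)
})

test_that("unknown ids in edits raise errors", {
  m <- build_toy_model(manifest = FALSE)
  expect_error(apply_edits(m, edit_set_bounds("NOPE", lb = 0)),
               "unknown reaction")
  expect_error(apply_edits(m, edit_add_reaction("X", c(nope_c = -1))),
               "unknown metabolite")
  expect_error(apply_edits(m, edit_remove_reaction("NOPE")),
               "unknown reaction")
})

test_that("edit directives round-trip through a YAML file", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    list(action = "set_bounds", id = "EX_glc", lb = -4),
    list(action = "add_coupling", target = "ATPM", source = "EX_glc",
         ratio = -5)), f)
  m <- build_toy_model(toy_model_spec(include_ngam = FALSE),
                       manifest = FALSE)
  m2 <- apply_edits(m, f)
  expect_equal(m2$reactions$lb[m2$reactions$id == "EX_glc"], -4)
  expect_equal(nrow(m2$couplings), 1)
})

test_that("gene rules evaluate AND/OR logic and reject malformed input", {
  expect_true(gpr_eval("", "g1"))
  expect_true(gpr_eval("(g1 and g2) or g3", "g1"))
  expect_false(gpr_eval("(g1 and g2) or g3", c("g1", "g3")))
  expect_false(gpr_eval("g1 and g2", "g2"))
  expect_setequal(gpr_genes("(g1 and g2) or g3"), c("g1", "g2", "g3"))
  expect_error(gpr_eval("g1 and and g2"), "malformed")
})
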