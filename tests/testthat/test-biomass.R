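# Variable-lipid biomass equations and the split maintenance model.

test_that("reference lipid fraction reproduces the base composition", {
  spec <- toy_biomass_spec(f_NL = 0.004)   # equals reference_f
  ed <- build_biomass(spec, tag = "tag_c", atp = "atp_c", adp = "adp_c")
  sto <- ed$stoichiometry
  expect_equal(unname(sto["pyr_c"]),
               -unname(spec$base_composition["pyr_c"]), tolerance = 1e-12)
  expect_equal(unname(sto["atp_c"]), -17.05)
  expect_equal(unname(sto["adp_c"]), 17.05)
})

test_that("60 % lipid delivers 0.60 g TAG and rescales the rest", {
  spec <- toy_biomass_spec(f_NL = 0.60)
  ed <- build_biomass(spec, tag = "tag_c", atp = "atp_c", adp = "adp_c")
  sto <- ed$stoichiometry
  mw_tag <- tag_weight(spec$fa_profile, spec$fa_mw)
  expect_equal(unname(-sto["tag_c"]) * mw_tag / 1000, 0.60,
               tolerance = 1e-9)
  scale <- (1 - 0.60) / (1 - spec$reference_f)
  expect_equal(unname(sto["pyr_c"]),
               -unname(spec$base_composition["pyr_c"]) * scale,
               tolerance = 1e-12)
  # mass summation oracle from the component molecular weights
  mass <- unname(-sto["pyr_c"]) * 88.062 / 1000 +
    unname(-sto["tag_c"]) * mw_tag / 1000
  expect_equal(mass, 1, tolerance = 0.005)
})

test_that("the whole lipid-fraction series conserves 1 g biomass per gDW", {
  for (f in c(0.004, 0.01, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8)) {
    spec <- toy_biomass_spec(f_NL = f)
    ed <- build_biomass(spec, tag = "tag_c", atp = "atp_c", adp = "adp_c")
    expect_equal(attr(ed, "mass"), 1, tolerance = 0.005)
  }
  expect_error(toy_biomass_spec(f_NL = 0.001), "outside")
  expect_error(toy_biomass_spec(f_NL = 0.9), "outside")
  expect_error(biomass_spec(0.1, c(x = 1), c(y = 1)),
               "missing molecular weight")
})

test_that("growth declines monotonically with lipid content at fixed uptake", {
  m <- build_toy_model(manifest = FALSE)
  m <- set_uptake(m, "EX_glc", 4, fix = TRUE)
  mus <- vapply(c(0.004, 0.1, 0.2, 0.4, 0.6, 0.8), function(f) {
    mf <- set_biomass(m, toy_biomass_spec(f_NL = f), tag = "tag_c",
                      atp = "atp_c", adp = "adp_c")
    solve_fba(mf, "BIOMASS", "max")$objective_value
  }, numeric(1))
  expect_true(all(diff(mus) <= 1e-8))
  expect_gt(mus[1], 0)
})

test_that("raising either maintenance term never raises growth", {
  base <- build_toy_model(toy_model_spec(include_ngam = FALSE),
                          manifest = FALSE)
  base <- set_uptake(base, "EX_glc", 4, fix = TRUE)
  mu_for <- function(gam, ngam) {
    m <- set_biomass(base, toy_biomass_spec(gam = gam), tag = "tag_c",
                     atp = "atp_c", adp = "adp_c")
    m <- set_maintenance(m, ngam_ratio = ngam, substrate = "EX_glc",
                         atp = "atp_c", adp = "adp_c")
    solve_fba(m, "BIOMASS", "max")$objective_value
  }
  gams <- vapply(c(0, 10, 17.05, 40), mu_for, numeric(1), ngam = 1)
  expect_true(all(diff(gams) <= 1e-8))
  ngams <- vapply(c(0, 1, 2.28, 5), mu_for, numeric(1), gam = 17.05)
  expect_true(all(diff(ngams) <= 1e-8))
})

test_that("set_maintenance writes GAM into the biomass reaction", {
  m <- build_toy_model(manifest = FALSE)
  m2 <- set_maintenance(m, ngam_ratio = 1, substrate = "EX_glc",
                        atp = "atp_c", adp = "adp_c", gam = 25)
  j <- match("BIOMASS", m2$reactions$id)
  expect_equal(m2$S[match("atp_c", m2$metabolites$id), j], -25)
  expect_equal(m2$S[match("adp_c", m2$metabolites$id), j], 25)
  expect_error(set_maintenance(m, 1, substrate = "EX_nope",
                               atp = "atp_c", adp = "adp_c"),
               "unknown substrate")
})
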