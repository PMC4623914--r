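# FBA, FVA, robustness scans, couplings and gene deletions.

test_that("FBA on the chain model hits the uptake bound", {
  m <- chain_model(uptake = 5)
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5)
  expect_lt(sol$residual, 1e-6)
})

test_that("closing every uptake forces zero growth", {
  m <- close_uptakes(build_toy_model(manifest = FALSE))
  sol <- solve_fba(m, "BIOMASS", "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("infeasible constraint sets are reported as status, not crashes", {
  m <- build_toy_model(manifest = FALSE)
  # demand a growth rate the carbon supply cannot sustain
  m <- apply_edits(m, edit_set_bounds("BIOMASS", lb = 100, ub = 100))
  sol <- solve_fba(m, "BIOMASS", "max")
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("parsimonious resolution keeps the objective and is idempotent", {
  m <- build_toy_model(manifest = FALSE)
  plain <- solve_fba(m, "BIOMASS", "max")
  pars <- solve_fba(m, "BIOMASS", "max", parsimonious = TRUE)
  expect_equal(pars$objective_value, plain$objective_value,
               tolerance = 1e-9)
  expect_lte(sum(abs(pars$fluxes)), sum(abs(plain$fluxes)) + 1e-6)
  expect_lt(pars$residual, 1e-6)
  # pin every flux at the parsimonious solution: re-solving changes nothing
  m2 <- m
  m2$reactions$lb <- pars$fluxes - 1e-7
  m2$reactions$ub <- pars$fluxes + 1e-7
  again <- solve_fba(m2, "BIOMASS", "max", parsimonious = TRUE)
  expect_equal(again$fluxes, pars$fluxes, tolerance = 1e-5)
})

test_that("FVA brackets the optimum flux and honours fixed bounds", {
  m <- build_toy_model(manifest = FALSE)
  pars <- solve_fba(m, "BIOMASS", "max", parsimonious = TRUE)
  fva <- flux_variability(m, fraction_of_optimum = 1)
  expect_true(all(fva$min <= fva$max + 1e-9))
  v <- pars$fluxes[fva$reaction]
  expect_true(all(v >= fva$min - 1e-6 & v <= fva$max + 1e-6))
  # a reaction pinned to a value has min = max = that value
  m2 <- apply_edits(m, edit_set_bounds("ATPM", lb = 10, ub = 10))
  fva2 <- flux_variability(m2, "ATPM", fraction_of_optimum = 1)
  expect_equal(fva2$min, 10, tolerance = 1e-9)
  expect_equal(fva2$max, 10, tolerance = 1e-9)
})

test_that("objective value is invariant under reaction reordering", {
  base <- solve_fba(build_toy_model(manifest = FALSE), "BIOMASS",
                    "max")$objective_value
  for (seed in c(3, 17, 23)) {
    m <- build_toy_model(toy_model_spec(seed = seed), manifest = FALSE)
    sol <- solve_fba(m, "BIOMASS", "max")
    expect_equal(sol$objective_value, base, tolerance = 1e-9)
  }
})

test_that("flux couplings enforce the maintenance arithmetic", {
  # 5 mmol ATP per mmol glucose at uptake 4 -> maintenance flux 20
  m <- build_toy_model(toy_model_spec(include_ngam = FALSE),
                       manifest = FALSE)
  m <- set_maintenance(m, ngam_ratio = 5, substrate = "EX_glc",
                       atp = "atp_c", adp = "adp_c")
  m <- set_uptake(m, "EX_glc", 4, fix = TRUE)
  sol <- solve_fba(m, "BIOMASS", "max")
  expect_equal(unname(sol$fluxes[["ATPM"]]), 20, tolerance = 1e-8)
  # glycerol-parameterised ratio: 2.28 * 8.78 = 20.02
  m2 <- build_toy_model(toy_model_spec(include_ngam = FALSE,
                                       glc_uptake = 20), manifest = FALSE)
  m2 <- set_maintenance(m2, ngam_ratio = 2.28, substrate = "EX_glc",
                        atp = "atp_c", adp = "adp_c")
  m2 <- set_uptake(m2, "EX_glc", 8.78, fix = TRUE)
  sol2 <- solve_fba(m2, "BIOMASS", "max")
  expect_equal(unname(sol2$fluxes[["ATPM"]]), 2.28 * 8.78,
               tolerance = 1e-8)
  # ratio 0: maintenance flux 0 regardless of uptake
  m3 <- set_maintenance(m, ngam_ratio = 0, substrate = "EX_glc",
                        atp = "atp_c", adp = "adp_c")
  sol3 <- solve_fba(m3, "BIOMASS", "max")
  expect_equal(unname(sol3$fluxes[["ATPM"]]), 0, tolerance = 1e-9)
  # self-coupling is rejected
  expect_error(couple_fluxes(m, "ATPM", "ATPM", 1), "itself")
})

test_that("a one-point robustness scan equals a plain solve", {
  m <- build_toy_model(manifest = FALSE)
  cur <- -m$reactions$lb[m$reactions$id == "EX_o2"]
  rc <- robustness_scan(m, "EX_o2", cur, objectives = "BIOMASS")
  sol <- solve_fba(m, "BIOMASS", "max")
  expect_equal(rc$objective_BIOMASS, sol$objective_value,
               tolerance = 1e-9)
})

test_that("growth responds monotonically to the oxygen bound, with overflow at zero", {
  m <- build_toy_model(toy_model_spec(include_pyr_export = TRUE),
                       manifest = FALSE)
  # cells keep importing glucose while oxygen runs out
  m <- set_uptake(m, "EX_glc", 4, fix = TRUE)
  rc <- robustness_scan(m, "EX_o2", seq(0, 12, by = 1),
                        objectives = list("BIOMASS", "DM_tag"),
                        reporters = "EX_pyr")
  expect_true(all(rc$status == "optimal"))
  expect_true(all(diff(rc$objective_BIOMASS) >= -1e-8))
  # anaerobic point: fermentative pyruvate overflow from the growth solve
  expect_gt(rc$flux_EX_pyr[rc$bound == 0], 0)
  # grid must be monotone
  expect_error(robustness_scan(m, "EX_o2", c(1, 3, 2), "BIOMASS"),
               "monotone")
})

test_that("infeasible grid points are recorded and the scan continues", {
  m <- build_toy_model(manifest = FALSE)
  # force a growth floor that low oxygen cannot sustain
  m <- apply_edits(m, edit_set_bounds("BIOMASS", lb = 1))
  rc <- robustness_scan(m, "EX_o2", c(0, 12), objectives = "BIOMASS")
  expect_equal(rc$status, c("infeasible", "optimal"))
  expect_true(is.na(rc$objective_BIOMASS[1]))
  expect_false(is.na(rc$objective_BIOMASS[2]))
})

test_that("single-gene deletions classify transporters, isozymes and absent genes", {
  m <- build_toy_model(manifest = FALSE)
  dr <- single_gene_deletions(m)
  ratios <- setNames(dr$growth_ratio, dr$gene)
  # sole glucose transporter: lethal
  expect_equal(unname(ratios["YL_HXT1"]), 0)
  expect_true(dr$essential[dr$gene == "YL_HXT1"])
  # isoenzyme pair (NDH1 OR NDH2): each deletion alone is silent
  expect_equal(unname(ratios["YL_NDH1"]), 1)
  expect_equal(unname(ratios["YL_NDH2"]), 1)
  expect_true(all(dr$growth_ratio >= 0 & dr$growth_ratio <= 1))
  # a gene absent from all rules has ratio exactly 1
  m2 <- chain_model()
  m2$genes <- c(m2$genes, "ghost")
  dr2 <- single_gene_deletions(m2)
  expect_equal(dr2$growth_ratio[dr2$gene == "ghost"], 1)
})

test_that("every optimal solution satisfies steady state to 1e-6", {
  m <- build_toy_model(toy_model_spec(include_idh = TRUE,
                                      include_thd = TRUE,
                                      include_pyr_export = TRUE),
                       manifest = FALSE)
  for (obj in list("BIOMASS", "DM_tag", c(BIOMASS = 1, DM_tag = 2))) {
    sol <- solve_fba(m, obj, "max", parsimonious = TRUE)
    expect_equal(sol$status, "optimal")
    expect_lt(sol$residual, 1e-6)
  }
})
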