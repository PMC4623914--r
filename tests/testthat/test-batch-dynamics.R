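# Dynamic FBA batch simulation and yield extraction.

test_that("constant-mu growth matches the exponential closed form", {
  m <- build_toy_model(toy_model_spec(glc_uptake = 1000), manifest = FALSE)
  cap <- 4
  # plenty of substrate so the cap binds throughout: mu is constant and the
  # per-step exponential update reproduces X0 * exp(mu t) to round-off
  mu <- solve_fba(set_uptake(m, "EX_glc", cap, fix = TRUE),
                  "BIOMASS", "max")$objective_value
  traj <- simulate_batch(m, 0.01, list(EX_glc = 500), c(EX_glc = cap),
                         dt = 0.25, t_end = 4)
  exact <- 0.01 * exp(mu * 4)
  expect_equal(tail(traj$biomass, 1), exact, tolerance = 1e-8)
})

test_that("halving dt shrinks the endpoint error at first order", {
  # single-substrate batches are integrated exactly (piecewise-constant LP
  # response, exponential biomass update); step-size error appears when
  # two substrate bounds interact, here glucose plus co-consumed citrate
  m <- build_toy_model(manifest = FALSE)
  m <- apply_edits(m, list(edit_set_bounds("EX_cit", lb = -1000),
                           edit_set_bounds("CITt", lb = -1000)))
  run <- function(dt) {
    tr <- simulate_batch(m, 0.01, list(EX_glc = 3, EX_cit = 3),
                         c(EX_glc = 4, EX_cit = 2), dt = dt, t_end = 60)
    tail(tr$biomass, 1)
  }
  ref <- run(0.00625)
  e1 <- abs(run(0.1) - ref)
  e2 <- abs(run(0.05) - ref)
  e3 <- abs(run(0.025) - ref)
  expect_lt(e2, 0.75 * e1)
  expect_lt(e3, 0.75 * e2)
})

test_that("starting without substrate gives a flat, immediately terminated run", {
  m <- build_toy_model(manifest = FALSE)
  traj <- simulate_batch(m, 0.5, list(EX_glc = 0), c(EX_glc = 4),
                         dt = 0.1, t_end = 10)
  expect_equal(nrow(traj), 1)
  expect_equal(attr(traj, "terminal_reason"), "substrate_exhausted")
  expect_equal(traj$biomass, 0.5)
})

test_that("batch runs exhaust the substrate without negative concentrations", {
  m <- build_toy_model(manifest = FALSE)
  traj <- simulate_batch(m, 0.003, list(EX_glc = 20, EX_co2 = 0),
                         c(EX_glc = 4), dt = 0.1, t_end = 100)
  expect_equal(attr(traj, "terminal_reason"), "substrate_exhausted")
  expect_true(all(traj$EX_glc >= 0))
  expect_true(all(diff(traj$time) > 0))
  expect_true(all(diff(traj$biomass) >= -1e-9))
})

test_that("carbon in consumed glucose covers biomass plus excreted CO2", {
  m <- build_toy_model(manifest = FALSE)
  traj <- simulate_batch(m, 0.003, list(EX_glc = 20, EX_co2 = 0),
                         c(EX_glc = 4), dt = 0.1, t_end = 100)
  n <- nrow(traj)
  # everything in mmol carbon per litre
  glc_C <- (traj$EX_glc[1] - traj$EX_glc[n]) / 180.156 * 6 * 1000
  co2_C <- (traj$EX_co2[n] - traj$EX_co2[1]) / 44.009 * 1000
  # carbon drained per unit biomass flux (mmol C per gDW), from the
  # biomass stoichiometry
  biomass_C_per_g <- reaction_carbon_drain(m, "BIOMASS")
  x_C <- (traj$biomass[n] - traj$biomass[1]) * biomass_C_per_g
  expect_gte(glc_C + 1e-6, x_C)
  expect_equal(glc_C, x_C + co2_C, tolerance = 0.02)
})

test_that("trajectory yields match the instantaneous stoichiometric yield", {
  m <- build_toy_model(manifest = FALSE)
  cap <- 4
  # single step: the yield is the stoichiometric one
  one <- simulate_batch(m, 0.1, list(EX_glc = 50), c(EX_glc = cap),
                        dt = 0.1, t_end = 0.1)
  y1 <- trajectory_yields(one, "EX_glc")
  sol <- solve_fba(set_uptake(m, "EX_glc", cap, fix = TRUE),
                   "BIOMASS", "max")
  y_static <- sol$objective_value / (cap * 180.156 / 1000)
  expect_equal(y1$Y_SX, y_static, tolerance = 0.02)
  # a full batch with the cap binding throughout gives the same yield
  full <- simulate_batch(m, 0.003, list(EX_glc = 20), c(EX_glc = cap),
                         dt = 0.05, t_end = 100)
  yf <- trajectory_yields(full, "EX_glc")
  expect_equal(yf$Y_SX, y_static, tolerance = 0.02)
  expect_error(trajectory_yields(one, "EX_glc_missing"))
})
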