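# Lipogenesis optimization, feed-rate calculation, lipid-content scans,
# oxygen thresholds, NADPH-source comparison, theoretical yields, screens.

lipo_model <- function(...) {
  build_toy_model(toy_model_spec(include_pyr_export = TRUE, ...),
                  manifest = FALSE)
}

test_that("lipogenesis optimum responds to uptake and the citrate constraint", {
  m <- lipo_model()
  map <- toy_map()
  cons <- lipogenesis_constraints(substrate_uptake = 0.35, citrate = 0.55)
  res <- lipogenesis_fba(m, cons, map)
  expect_gt(res$lipid_flux, 0)
  expect_gt(res$acl_flux, 0)
  expect_gt(res$nadph_production, 0)
  # removing the citrate drain redirects that carbon into lipid
  free_ <- lipogenesis_fba(m, lipogenesis_constraints(0.35, NULL), map)
  expect_gt(free_$lipid_flux, res$lipid_flux)
  # zero uptake: no lipid
  zero <- lipogenesis_fba(m, lipogenesis_constraints(0, NULL), map)
  expect_equal(zero$lipid_flux, 0, tolerance = 1e-9)
  # the solution respects the pinned citrate excretion
  expect_equal(unname(res$solution$fluxes[["EX_cit"]]), 0.55 * 0.35,
               tolerance = 1e-8)
})

test_that("feed uptake equals the hand-solved stoichiometric minimum", {
  # With the PPP as sole NADPH source and glucose the only carbon input,
  # one TAG needs 24 glucose through citrate synthesis (8 acetyl-CoA per
  # acyl chain x 3), 3.5 through the PPP (42 NADPH at 12 per glucose) and
  # 0.5 for the backbone: 28 mmol glucose per mmol TAG. NGAM scales with
  # uptake, so the floor at target 0 is 0.
  m <- lipo_model()
  map <- toy_map()
  expect_equal(compute_feed_uptake(m, 0.1, map), 2.8, tolerance = 1e-6)
  expect_equal(compute_feed_uptake(m, 0, map), 0, tolerance = 1e-9)
  # always at most the unrestricted lipogenesis uptake that produced the
  # same lipid flux alongside citrate overflow
  cons <- lipogenesis_constraints(substrate_uptake = 0.35, citrate = 0.55)
  res <- lipogenesis_fba(m, cons, map)
  up <- compute_feed_uptake(m, res$lipid_flux, map)
  expect_lte(up, 0.35 + 1e-9)
  expect_error(compute_feed_uptake(m, 1e6, map), "unreachable")
})

test_that("feed schedule arithmetic is dimensionally consistent", {
  # 6.55 g/L fed at 69.4 uL/min delivers 6.55 * 0.0694e-3 * 60 g/h
  expect_equal(feed_delivery(6.55, 69.4), 6.55 * 69.4e-6 * 60)
  expect_equal(feed_delivery(6.55, 69.4), 0.0273, tolerance = 0.01)
  plan <- feed_schedule(target_uptake = 0.152, biomass = 1.0,
                        feed_concentration = 6.55,
                        substrate_mw = 180.16)
  expect_equal(plan$delivery_g_h,
               feed_delivery(6.55, plan$pump_rate_uL_min),
               tolerance = 1e-9)
  expect_equal(feed_schedule(0, 1, 6.55)$pump_rate_uL_min, 0)
  # doubling the feed concentration halves the pump rate
  p1 <- feed_schedule(0.2, 2, 5); p2 <- feed_schedule(0.2, 2, 10)
  expect_equal(p1$pump_rate_L_h, 2 * p2$pump_rate_L_h)
})

test_that("lipid-content scans move growth, uptake and ATP:citrate lyase as expected", {
  m <- lipo_model()
  map <- toy_map()
  grid <- c(0.004, 0.2, 0.4, 0.6)
  up <- lipid_content_scan(m, toy_biomass_spec(), grid, "fixed_uptake",
                           map, uptake = 4)
  expect_true(all(up$status == "optimal"))
  expect_true(all(diff(up$mu) <= 1e-8))          # growth falls with f
  expect_true(all(diff(up$acl_flux) >= -1e-8))   # lipid route rises with f
  gr <- lipid_content_scan(m, toy_biomass_spec(), grid, "fixed_growth",
                           map, growth = 0.3)
  expect_true(all(gr$status == "optimal"))
  expect_true(all(diff(gr$uptake) >= -1e-8))     # uptake rises with f
  # a single point at the model's own biomass equals a plain solve
  one <- lipid_content_scan(m, toy_biomass_spec(f_NL = 0.05), 0.05,
                            "fixed_uptake", map, uptake = 4)
  plain <- solve_fba(set_uptake(m, "EX_glc", 4, fix = TRUE),
                     "BIOMASS", "max")
  expect_equal(one$mu, plain$objective_value, tolerance = 1e-8)
})

test_that("oxygen thresholds: growth is oxygen-starved before lipid synthesis", {
  # scan at the measured growth-phase uptake, as the study design does
  m <- set_uptake(lipo_model(), "EX_glc", 4, fix = TRUE)
  map <- toy_map()
  grid <- seq(0, 12, by = 0.25)
  rc <- robustness_scan(m, "EX_o2", grid,
                        objectives = list("BIOMASS", "DM_tag"))
  th <- o2_thresholds(rc, c("objective_BIOMASS", "objective_DM_tag"))
  expect_false(anyNA(th))
  expect_gte(th[["objective_BIOMASS"]], th[["objective_DM_tag"]])
  # lipid objective is flat above its threshold
  top <- rc$objective_DM_tag[rc$bound >= th[["objective_DM_tag"]] + 0.5]
  expect_lt(diff(range(top)), 1e-6 * (1 + max(top)))
})

test_that("NADPH restriction is invertible and ranks sources correctly", {
  m <- build_toy_model(toy_model_spec(include_thd = TRUE,
                                      include_idh = TRUE,
                                      include_pyr_export = TRUE),
                       manifest = FALSE)
  map <- toy_map()
  prod <- nadph_producers(m, "nadph_c")
  expect_setequal(prod$reaction, c("PPP", "THD", "IDHy"))
  r <- restrict_nadph_source(m, "PPP", "nadph_c")
  expect_equal(r$reactions$ub[r$reactions$id == "THD"], 0)
  back <- unrestrict_nadph(r)
  expect_equal(back$reactions[, c("id", "lb", "ub")],
               m$reactions[, c("id", "lb", "ub")])
  expect_error(restrict_nadph_source(m, "GLYC", "nadph_c"),
               "produces no NADPH")
  cons <- lipogenesis_constraints(substrate_uptake = 0.35, citrate = 0.55)
  cmp <- nadph_yield_comparison(
    m, list(PPP = "PPP", IDH = "IDHy", THD = "THD"), cons, map)
  y <- setNames(cmp$yield, cmp$source)
  # the PPP beats every other single carbon-coupled source; an
  # energy-independent transhydrogenase beats the PPP
  expect_gte(y[["PPP"]], y[["IDH"]] - 1e-9)
  expect_gte(y[["THD"]], y[["PPP"]] - 1e-9)
  expect_equal(cmp$relative[cmp$source == "PPP"], 1)
})

test_that("the pattern file resolves NADPH source sets per model", {
  m <- build_toy_model(toy_model_spec(include_thd = TRUE,
                                      include_idh = TRUE),
                       manifest = FALSE)
  src <- nadph_source_sets(m)
  expect_equal(src$PPP, "PPP")
  expect_equal(src$IDH_cyt, "IDHy")
  expect_equal(src$TRANSHYDROGENASE, "THD")
  expect_length(src$MANNITOL_CYCLE, 0)   # not in the core model
  # every NADPH producer of this model is covered by exactly one source
  prod <- nadph_producers(m, "nadph_c")
  hits <- vapply(prod$reaction, function(r)
    sum(vapply(src, function(s) r %in% s, logical(1))), integer(1))
  expect_true(all(hits == 1))
})

test_that("theoretical yields: citrate caps at 1 mol/mol glucose", {
  m <- lipo_model()
  map <- toy_map()
  ty <- theoretical_yield(m, "EX_cit", "EX_glc", map)
  expect_equal(ty$mol_per_mol, 1, tolerance = 1e-8)
  expect_equal(ty$g_per_g, 192.12 / 180.16, tolerance = 0.01)
  expect_equal(ty$percent_of_theoretical(ty$g_per_g / 2), 50,
               tolerance = 1e-6)
  # unreachable product reports a zero yield with a diagnostic
  m2 <- apply_edits(m, edit_set_bounds("CITt", lb = 0, ub = 0))
  expect_message(ty2 <- theoretical_yield(m2, "EX_cit", "EX_glc", map),
                 "unreachable")
  expect_equal(ty2$mol_per_mol, 0)
})

test_that("substrate screen builds the planted confusion matrix", {
  fx <- toy_screen_fixture()
  rep_ <- substrate_screen(fx$model, fx$substrates, fx$truth,
                           fx$free_exchanges)
  cm <- attr(rep_, "confusion")
  expect_equal(unname(cm["FP"]), 1)
  expect_equal(attr(rep_, "accuracy"), 0.75)
  expect_equal(sum(cm), length(fx$substrates))
  # sucrose: exchange present, no hydrolysis route, so no growth predicted
  expect_false(rep_$predicted[rep_$substrate == "EX_sucr"])
  # with truth replaced by the predictions, accuracy is 1
  truth2 <- setNames(rep_$predicted, rep_$substrate)
  rep2 <- substrate_screen(fx$model, fx$substrates, truth2,
                           fx$free_exchanges)
  expect_equal(attr(rep2, "accuracy"), 1)
  expect_error(substrate_screen(fx$model, character(), fx$truth,
                                fx$free_exchanges), "empty substrate")
  # a substrate without an exchange is untestable and excluded
  rep3 <- substrate_screen(fx$model, c(fx$substrates, "EX_xyl"),
                           c(fx$truth, EX_xyl = TRUE), fx$free_exchanges)
  expect_false(rep3$testable[rep3$substrate == "EX_xyl"])
  expect_equal(sum(attr(rep3, "confusion")), 4)
})

test_that("citrate-node split matches overflow accounting at the optimum", {
  # at the lipogenesis optimum the citrate formed per glucose splits into
  # excretion plus the ATP:citrate lyase (lipid) route
  m <- lipo_model()
  map <- toy_map()
  cons <- lipogenesis_constraints(substrate_uptake = 0.35, citrate = 0.55)
  res <- lipogenesis_fba(m, cons, map)
  v <- res$solution$fluxes
  cit_total <- v[["CITSYN"]]
  expect_equal(cit_total, v[["EX_cit"]] + v[["ACL"]], tolerance = 1e-8)
  expect_equal(v[["EX_cit"]] / 0.35, 0.55, tolerance = 1e-8)
})
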