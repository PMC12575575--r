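test_that("scenario validation rejects bad combinations", {
  expect_error(scenario_spec(horizon_years = 47), "divisible")
  reg <- generate_catchment(catchment_config(n_compartments = 40, seed = 2))
  expect_error(run_scenario(reg, scenario_spec("ERP", seed = 2)),
               "not defined for drained peatland")
  regm <- subset_register(reg, "mineral")
  expect_s3_class(run_scenario(regm, scenario_spec("ERP", seed = 2)),
                  "scenario_result")
})

test_that("without management, mineral forests with no history export nothing", {
  cmp <- mono_stand(18, 20, id = "m1")
  reg <- tiny_register(list(cmp))
  res <- run_scenario(reg, scenario_spec("none", seed = 1))
  expect_equal(nrow(res$ledger), 0L)
  expect_true(all(res$harvest_series$harvest_m3_ha_yr == 0))
})

test_that("drained peatlands export legacy nutrients every year even unmanaged", {
  cmp <- mono_stand(22, 24, land_class = "drained_peat", fertility = "mesic",
                    species = "pine", id = "p1", years_since_dnm = 20)
  res <- run_scenario(tiny_register(list(cmp)), scenario_spec("none", seed = 1))
  lg <- res$ledger
  expect_true(all(lg$source == "legacy"))
  n_years <- sort(unique(lg$year[lg$nutrient == "N"]))
  expect_equal(n_years, 1:50)
  expect_true(all(lg$kg > 0))
})

test_that("continuous cover forestry triggers no ditch maintenance over the horizon", {
  reg <- generate_catchment(catchment_config(n_compartments = 200, seed = 31))
  regp <- subset_register(reg, "drained_peat")
  ccf <- run_scenario(regp, scenario_spec("CCF", seed = 31))
  expect_equal(sum(ccf$events$event_type == "dnm"), 0L)
  rf <- run_scenario(regp, scenario_spec("RF", seed = 31))
  expect_gt(sum(rf$events$event_type == "dnm"), 0L)
})

test_that("pre-simulation clear-cuts surface as first-period residual exports", {
  cmp <- mono_stand(4, 1, id = "m1", fertility = "mesic", species = "spruce",
                    age = 3)
  events <- tibble::tibble(
    compartment_id = "m1", event_type = "clear_cut", year = -3L,
    removed_volume_m3_ha = 200, treated_area_ha = cmp$area_ha
  )
  reg <- tiny_register(list(cmp), events)
  res <- run_scenario(reg, scenario_spec("none", seed = 1))
  lg <- res$ledger
  # a year -3 felling contributes schedule years 5..10 = calendar years 1..6
  expect_equal(sort(unique(lg$year)), 1:6)
  expect_equal(lg$kg_ha[lg$nutrient == "N" & lg$year == 1],
               coefficient_lookup("clearcut_mineral", "N", 5))
  expect_true(all(lg$year <= 10))
})

test_that("accumulated series are nondecreasing and conserve mass", {
  reg <- generate_catchment(catchment_config(n_compartments = 150, seed = 17))
  regp <- subset_register(reg, "drained_peat")
  res <- run_scenario(regp, scenario_spec("RF", "wetlands", seed = 17))
  lg <- res$ledger
  expect_true(all(lg$kg >= 0))
  expect_true(all(lg$retained_kg <= lg$kg + 1e-12))
  expect_true(all(lg$retained_kg >= 0))
  # delivered = generated - retained, ledger-wide
  delivered <- sum(lg$kg) - sum(lg$retained_kg)
  acc_n <- accumulate_exports(res, "drained_peat", "N")
  acc_p <- accumulate_exports(res, "drained_peat", "P")
  expect_true(all(diff(acc_n$cumulative_kg_ha) >= 0))
  expect_true(all(diff(acc_p$cumulative_kg_ha) >= 0))
  total_acc <- (tail(acc_n$cumulative_kg_ha, 1) + tail(acc_p$cumulative_kg_ha, 1)) *
    res$class_areas[["drained_peat"]]
  expect_equal(total_acc, delivered, tolerance = 1e-9)
})

test_that("accumulate handles unit and empty cases", {
  empty <- tibble::tibble(
    compartment_id = character(), land_class = character(),
    fertility = character(), area_ha = numeric(), year = integer(),
    source = character(), nutrient = character(), kg_ha = numeric(),
    particulate = logical(), kg = numeric(), retained_kg = numeric()
  )
  z <- accumulate_exports(empty, "mineral", "N", horizon_years = 5,
                          class_area_ha = 1)
  expect_equal(z$cumulative_kg_ha, rep(0, 5))

  one <- tibble::tibble(
    compartment_id = "c1", land_class = "mineral", fertility = "mesic",
    area_ha = 1, year = 3L, source = "harvest", nutrient = "N", kg_ha = 2,
    particulate = FALSE, kg = 2, retained_kg = 0
  )
  s <- accumulate_exports(one, "mineral", "N", horizon_years = 5,
                          class_area_ha = 1)
  expect_equal(s$cumulative_kg_ha, c(0, 0, 2, 2, 2))
})

test_that("identical inputs and seed give byte-identical ledgers", {
  reg <- generate_catchment(catchment_config(n_compartments = 100, seed = 4))
  regp <- subset_register(reg, "drained_peat")
  a <- run_scenario(regp, scenario_spec("RF", seed = 99))
  b <- run_scenario(regp, scenario_spec("RF", seed = 99))
  expect_identical(a$ledger$kg, b$ledger$kg)
  expect_identical(a$events, b$events)
  c <- run_scenario(regp, scenario_spec("RF", seed = 100))
  expect_false(identical(a$events, c$events))
})

test_that("per-source class totals add up to the class total", {
  reg <- generate_catchment(catchment_config(n_compartments = 120, seed = 23))
  regp <- subset_register(reg, "drained_peat")
  res <- run_scenario(regp, scenario_spec("RF", seed = 23))
  rep_ <- scenario_report(res)
  by_source <- sum(rep_$kg_per_ha_yr[rep_$nutrient == "N"]) * 10
  acc <- tail(accumulate_exports(res, "drained_peat", "N")$cumulative_kg_ha, 1)
  expect_equal(by_source, acc, tolerance = 1e-9)
})

test_that("harvest-export relation reports zero harvests for the no-management run", {
  reg <- generate_catchment(catchment_config(n_compartments = 60, seed = 6))
  regp <- subset_register(reg, "drained_peat")
  res <- run_scenario(regp, scenario_spec("none", seed = 6))
  rel <- harvest_export_relation(res)
  expect_true(all(rel$harvest_m3_ha_yr == 0))
  expect_true(all(rel$N_kg_ha_yr > 0))  # legacy continues regardless
})

test_that("mineral CCF exports vanish after the residual period regardless of harvests", {
  reg <- generate_catchment(catchment_config(n_compartments = 200, seed = 14))
  regm <- subset_register(reg, "mineral")
  res <- run_scenario(regm, scenario_spec("CCF", seed = 14))
  rel <- harvest_export_relation(res)
  later <- rel[rel$period > 1, ]
  expect_true(any(later$harvest_m3_ha_yr > 0))
  expect_true(all(later$N_kg_ha_yr == 0))
  expect_true(all(later$P_kg_ha_yr == 0))
})
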