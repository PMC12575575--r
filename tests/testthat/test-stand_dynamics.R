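test_that("planted and seeded stands grow exactly 1.10x and 1.05x faster in diameter", {
  base <- function(origin) make_stand(origin = origin, mids = 15, stems = 800)
  gp <- growth_params(ingrowth_stems_yr = 0)  # isolate the increment kernel
  inc <- function(origin) {
    grown <- grow_stand(base(origin), 1, growth = gp)
    grown$diameter_classes$mid_cm - 15
  }
  expect_equal(inc("planted") / inc("natural"), 1.10, tolerance = 1e-12)
  expect_equal(inc("seeded") / inc("natural"), 1.05, tolerance = 1e-12)
})

test_that("zero intrinsic increment leaves the stand unchanged except age", {
  cmp <- make_stand()
  gp <- growth_params(g0_cm_yr = 0, ingrowth_stems_yr = 0)
  grown <- grow_stand(cmp, 7, growth = gp)
  expect_equal(grown$diameter_classes, cmp$diameter_classes)
  expect_equal(grown$volume_m3_ha, cmp$volume_m3_ha)
  expect_equal(grown$age_years, cmp$age_years + 7)
})

test_that("cohort growth agrees with direct integration of the increment ODE", {
  skip_if_not_installed("deSolve")
  # single mesic-spruce cohort at V = 100 m3/ha, defaults, no ingrowth
  gp <- growth_params(ingrowth_stems_yr = 0)
  cl <- climate_constants()
  stems <- 900
  d0 <- (100 / (stems * gp$vol_a))^(1 / gp$vol_b)
  cmp <- make_stand(mids = d0, stems = stems, fertility = "mesic",
                    species = "spruce")
  expect_equal(cmp$volume_m3_ha, 100, tolerance = 1e-9)
  grown <- grow_stand(cmp, 10, growth = gp, climate = cl)

  rate <- gp$g0_cm_yr * gp$fertility_mult[["mesic"]] *
    gp$species_mult[["spruce"]] * (cl$ts / gp$ts_ref)
  ode_fun <- function(t, y, p) {
    ba <- stems * pi * (y[1] / 200)^2
    list(rate * exp(-gp$ba_sens * ba))
  }
  sol <- deSolve::ode(c(d = d0), seq(0, 10, by = 0.1), ode_fun, NULL)
  d10 <- sol[nrow(sol), "d"]
  v10 <- stems * gp$vol_a * d10^gp$vol_b
  expect_lt(abs(grown$volume_m3_ha - v10) / v10, 0.01)
})

test_that("final-felling maturity uses a strict threshold and the ERP multiplier", {
  rules <- management_rules(
    final_felling_min_d = data.frame(
      species = "spruce", fertility = "mesic", min_d_cm = 24
    )
  )
  at <- function(d) mono_stand(d, 20)
  expect_true(check_final_felling(at(25), rules, "RF"))
  expect_false(check_final_felling(at(24), rules, "RF"))   # strict "exceeded"
  # 24 * 1.10 = 26.4 under extended rotation
  expect_false(check_final_felling(at(25), rules, "ERP"))
  expect_false(check_final_felling(at(26.4), rules, "ERP"))
  expect_true(check_final_felling(at(26.5), rules, "ERP"))
})

test_that("thinning removes half uniformly and half from the directed end", {
  # two cohorts tuned to 24 m2/ha total so the uniform half is exactly 1/6
  ba10 <- pi * (10 / 200)^2
  ba30 <- pi * (30 / 200)^2
  stems30 <- (24 - 1000 * ba10) / ba30
  cmp <- make_stand(mids = c(10, 30), stems = c(1000, stems30),
                    fertility = "mesic", species = "spruce", age = 60)
  expect_equal(cmp$basal_area_m2_ha, 24, tolerance = 1e-12)
  rules <- management_rules(
    thinning_limit_ba = 20, post_thinning_ba = 16,
    final_felling_min_d = data.frame(species = "spruce", fertility = "mesic",
                                     min_d_cm = 40)
  )

  # hand-computed plan, mode below: uniform 1/6 in both cohorts, the directed
  # 4 m2/ha all from the 10-cm cohort (its remaining 6.545 m2/ha suffices)
  below <- apply_thinning(cmp, "below", rules)
  exp10 <- 1000 * 5 / 6 - 4 / ba10
  exp30 <- stems30 * 5 / 6
  expect_equal(below$compartment$diameter_classes$stems_ha, c(exp10, exp30),
               tolerance = 1e-9)
  expect_equal(below$compartment$basal_area_m2_ha, 16, tolerance = 1e-9)

  # mode above: the directed 4 m2/ha comes from the 30-cm cohort
  above <- apply_thinning(cmp, "above", rules)
  expect_equal(above$compartment$diameter_classes$stems_ha,
               c(1000 * 5 / 6, stems30 * 5 / 6 - 4 / ba30), tolerance = 1e-9)
  expect_equal(above$compartment$basal_area_m2_ha, 16, tolerance = 1e-9)
  expect_gt(below$removed_volume_m3_ha, 0)
  expect_gt(above$removed_volume_m3_ha, below$removed_volume_m3_ha)
})

test_that("thinning is a no-op below the trigger basal area", {
  cmp <- mono_stand(15, 18)
  out <- apply_thinning(cmp, "below", management_rules(thinning_limit_ba = 24))
  expect_equal(out$removed_volume_m3_ha, 0)
  expect_equal(out$compartment$diameter_classes, cmp$diameter_classes)
})

test_that("continuous-cover harvest gates on the threshold and removes from above", {
  rules <- management_rules()
  low <- mono_stand(20, 10)
  expect_false(check_ccf_harvest(low, rules)$cut)

  cmp <- make_stand(mids = c(8, 14, 20, 26), stems = c(600, 500, 350, 200),
                    fertility = "mesic", species = "spruce")
  expect_gt(cmp$basal_area_m2_ha, 24)
  plan <- check_ccf_harvest(cmp, rules)
  expect_true(plan$cut)
  # intensity monotone nondecreasing toward larger cohorts
  expect_true(all(diff(plan$removal_fractions) >= -1e-12))
  # basal-area conservation of the plan
  ba_i <- c(600, 500, 350, 200) * pi * (c(8, 14, 20, 26) / 200)^2
  expect_equal(sum(plan$removal_fractions * ba_i), plan$remove_ba,
               tolerance = 1e-6)
})

test_that("fertilization windows follow the site, window and interval rules", {
  rules <- management_rules()
  peat <- function(elapsed, d = 15, ba = 20) {
    mono_stand(d, ba, land_class = "drained_peat", fertility = "sub_xeric",
               species = "pine", years_since_fertilization = elapsed)
  }
  expect_true(check_fertilization(peat(51), rules, "drained_peat", "RF"))
  expect_false(check_fertilization(peat(50), rules, "drained_peat", "RF"))
  expect_true(check_fertilization(peat(51), rules, "drained_peat", "CCF"))
  expect_false(check_fertilization(peat(51), rules, "drained_peat", "ERP"))

  mineral <- function(d, fertility = "xeric", species = "pine", elapsed = 11,
                      system = "RF") {
    check_fertilization(
      mono_stand(d, 20, fertility = fertility, species = species,
                 years_since_fertilization = elapsed),
      rules, "mineral", system
    )
  }
  expect_true(mineral(28))
  expect_false(mineral(28, system = "CCF"))        # even-aged only
  expect_false(mineral(20, "mesic", "spruce"))     # below the 23 cm window
  expect_false(mineral(28, "mesic", "pine"))       # ineligible site-species
  expect_false(mineral(28, elapsed = 10))          # strict > 10 years
})

test_that("ditch-network maintenance gates on volume, elapsed time and the felling trigger", {
  peat <- function(v_scale = 1, ysd = 35, d = 15, ba = 20) {
    cmp <- mono_stand(d, ba, land_class = "drained_peat",
                      fertility = "sub_xeric", species = "pine",
                      years_since_dnm = ysd)
    cmp
  }
  rules <- management_rules()
  expect_true(check_dnm(peat(), rules, after_final_felling = TRUE))
  expect_false(check_dnm(peat(), rules, after_final_felling = FALSE))
  expect_false(check_dnm(peat(ysd = 29), rules, after_final_felling = TRUE))
  # V = 160 m3/ha with everything else eligible: vetoed by the volume cap
  big <- mono_stand(28, 36, land_class = "drained_peat", fertility = "mesic",
                    species = "pine", years_since_dnm = 35)
  expect_gt(big$volume_m3_ha, 150)
  expect_false(check_dnm(big, rules, after_final_felling = TRUE))
  expect_error(check_dnm(make_stand(), rules), "drained_peat")
})

test_that("step_period emits no events without management and dates events mid-period", {
  cmp <- mono_stand(25, 26, land_class = "drained_peat", fertility = "mesic",
                    species = "pine", years_since_dnm = 35)
  out <- step_period(cmp, "none", period_index = 2)
  expect_equal(nrow(out$events), 0L)
  expect_length(out$annual_volumes, 10L)

  set.seed(1)
  rf <- step_period(cmp, "RF", period_index = 2)
  expect_true(all(rf$events$year %% 10 == 5))
})

test_that("a mature stand under RF is felled and regenerated in the same period", {
  set.seed(7)
  cmp <- mono_stand(27, 24, fertility = "mesic", species = "spruce", age = 90)
  out <- step_period(cmp, "RF", period_index = 1)
  types <- out$events$event_type
  expect_equal(sum(types == "clear_cut"), 1L)
  expect_true("site_preparation" %in% types)
  expect_true(any(types %in% c("planting", "seeding")))
  expect_true("tending" %in% types)
  expect_equal(out$events$year[types == "tending"], 15L)  # following period
  expect_equal(out$events$year[types == "clear_cut"], 5L)
  expect_lt(out$compartment$age_years, 10)
  expect_gt(out$events$removed_volume_m3_ha[types == "clear_cut"], 100)
})

test_that("a peat stand is fertilized at most once over five periods", {
  set.seed(3)
  cmp <- mono_stand(12, 14, land_class = "drained_peat", fertility = "sub_xeric",
                    species = "pine", years_since_dnm = 20,
                    years_since_fertilization = 60)
  events <- list()
  for (p in 1:5) {
    out <- step_period(cmp, "RF", period_index = p)
    cmp <- out$compartment
    events[[p]] <- out$events
  }
  ev <- dplyr::bind_rows(events)
  expect_lte(sum(ev$event_type == "fertilization_peat_ash"), 1L)
  expect_equal(sum(ev$event_type == "fertilization_peat_ash"), 1L)
})

test_that("harvest accounting conserves basal area and stems stay nonnegative", {
  set.seed(11)
  for (system in c("RF", "ERP", "CCF")) {
    cmp <- make_stand(mids = c(8, 16, 24, 28), stems = c(500, 450, 300, 150),
                      fertility = "mesic", species = "spruce")
    ba_before <- cmp$basal_area_m2_ha
    out <- step_period(cmp, system, period_index = 1,
                       growth = growth_params(g0_cm_yr = 0, ingrowth_stems_yr = 0))
    harv <- out$events[out$events$event_type %in%
                         c("thinning_below", "thinning_above", "ccf_harvest"), ]
    if (nrow(harv)) {
      target <- if (system == "CCF") management_rules()$ccf_residual_ba
                else management_rules()$post_thinning_ba
      expect_equal(out$compartment$basal_area_m2_ha, target, tolerance = 1e-6,
                   info = system)
    }
    expect_true(all(out$compartment$diameter_classes$stems_ha >= 0))
  }
})

test_that("ERP never fells a compartment earlier than RF", {
  reg <- generate_catchment(catchment_config(n_compartments = 120, seed = 21))
  regm <- subset_register(reg, "mineral")
  rf <- run_scenario(regm, scenario_spec("RF", seed = 21))
  erp <- run_scenario(regm, scenario_spec("ERP", seed = 21))
  first_cut <- function(res) {
    cuts <- res$events[res$events$event_type %in%
                         c("clear_cut", "seed_tree_felling") & res$events$year >= 1, ]
    tapply(cuts$year, cuts$compartment_id, min)
  }
  f_rf <- first_cut(rf); f_erp <- first_cut(erp)
  shared <- intersect(names(f_rf), names(f_erp))
  expect_true(all(f_erp[shared] >= f_rf[shared]))
  # every ERP-felled compartment is also felled under RF
  expect_true(all(names(f_erp) %in% names(f_rf)))
})

test_that("continuous cover forestry never clear-cuts", {
  reg <- generate_catchment(catchment_config(n_compartments = 150, seed = 8))
  for (lc in c("mineral", "drained_peat")) {
    res <- run_scenario(subset_register(reg, lc), scenario_spec("CCF", seed = 8))
    expect_false(any(res$events$event_type %in%
                       c("clear_cut", "seed_tree_felling") & res$events$year >= 1))
  }
})
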