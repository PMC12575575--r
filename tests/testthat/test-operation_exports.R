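test_that("the default coefficient table reproduces the printed schedules", {
  expect_equal(coefficient_lookup("dnm", "N", 1), 4.00)
  expect_equal(coefficient_lookup("dnm", "P", 1), 0.288)
  expect_equal(coefficient_lookup("dnm", "N", 1:10),
               c(4.00, 1.33, 1.07, 0.80, 0.67, 0.53, 0.40, 0.27, 0.13, 0.07))
  expect_equal(coefficient_lookup("clearcut_mineral", "N", 1), 1.43)
  expect_equal(coefficient_lookup("clearcut_mineral", "N", 3), 1.61)
  expect_equal(coefficient_lookup("clearcut_mineral", "P", 1:10),
               c(0.20, 0.21, 0.20, 0.18, 0.15, 0.13, 0.10, 0.08, 0.05, 0.03))
  expect_equal(coefficient_lookup("fert_mineral", "N", 1:3), c(12, 3, 0))
  expect_true(all(coefficient_lookup("fert_mineral", "P", 1:10) == 0))
  expect_true(all(coefficient_lookup("fert_peat", "N", 1:10) == 0))
  expect_equal(coefficient_lookup("fert_peat", "P", 1:6),
               c(0.27, 0.27, 0.27, 0.27, 0.27, 0))
  # schedule exhausted beyond year 10
  expect_equal(coefficient_lookup("dnm", "N", 11), 0)
  expect_equal(coefficient_lookup("clearcut_mineral", "P", 25), 0)
  expect_error(coefficient_lookup("stump_lifting", "N", 1), "unknown operation")
  expect_error(coefficient_lookup("dnm", "N", 0), ">= 1")
})

test_that("DNM nutrient ratios reflect a constant suspended-solids composition", {
  n <- coefficient_lookup("dnm", "N", 1:10)
  p <- coefficient_lookup("dnm", "P", 1:10)
  ratio <- p / n
  expect_true(all(abs(ratio - 0.072) < 0.005))
})

test_that("the logistic harvest-export curves match their closed forms", {
  # midpoint of the N curve: v_cut = 3.3375 / 0.0164
  expect_equal(harvest_export_peat(3.3375 / 0.0164, "N"), 5.0, tolerance = 1e-12)
  # midpoint of the P curve: v_cut = 5.1772 / 0.0209
  expect_equal(harvest_export_peat(5.1772 / 0.0209, "P"), 0.65, tolerance = 1e-12)
  # zero harvest leaves the residual intercept level
  expect_equal(harvest_export_peat(0, "N"), 10 / (1 + exp(3.3375)),
               tolerance = 1e-12)
  # asymptotes
  expect_lt(harvest_export_peat(1e6, "N"), 10 + 1e-9)
  expect_equal(harvest_export_peat(1e6, "N"), 10, tolerance = 1e-6)
  expect_equal(harvest_export_peat(1e6, "P"), 1.3, tolerance = 1e-6)
  # strictly increasing
  v <- seq(0, 500, by = 5)
  expect_true(all(diff(harvest_export_peat(v, "N")) > 0))
  expect_true(all(diff(harvest_export_peat(v, "P")) > 0))
  expect_error(harvest_export_peat(-1, "N"), ">= 0")
})

test_that("independent brute-force evaluation confirms the harvest curves on random inputs", {
  set.seed(77)
  v <- runif(100, 0, 400)
  oracle_n <- 10 * (1 + exp(3.3375 - 0.0164 * v))^-1
  oracle_p <- 1.3 * (1 + exp(5.1772 - 0.0209 * v))^-1
  expect_equal(harvest_export_peat(v, "N"), oracle_n, tolerance = 1e-9)
  expect_equal(harvest_export_peat(v, "P"), oracle_p, tolerance = 1e-9)
})

test_that("event schedules follow land class, duration and indexing rules", {
  mineral <- make_stand()
  peat_mesic <- make_stand(land_class = "drained_peat", fertility = "mesic",
                           species = "pine", years_since_dnm = 30)
  peat_xeric <- make_stand(land_class = "drained_peat", fertility = "xeric",
                           species = "pine", years_since_dnm = 30)
  ev <- function(type, year = 5, removed = 0) {
    list(event_type = type, year = year, removed_volume_m3_ha = removed)
  }

  # partial harvest on mineral soil exports nothing
  expect_equal(nrow(event_export_schedule(ev("thinning_below", removed = 50),
                                          mineral)), 0L)
  expect_equal(nrow(event_export_schedule(ev("ccf_harvest", removed = 80),
                                          mineral)), 0L)

  # mineral clear-cut: 10-year schedules, treatment year carries year 1;
  # year-3 N increment is 1.61 kg/ha
  cc <- event_export_schedule(ev("clear_cut", year = 5, removed = 200), mineral)
  n3 <- cc$kg_ha[cc$nutrient == "N" & cc$year == 7]
  expect_equal(n3, 1.61)
  expect_equal(range(cc$year), c(5, 14))
  expect_false(any(cc$particulate))

  # peat CCF harvest at 100 m3/ha on a mesic site: six equal annual values
  p <- event_export_schedule(ev("ccf_harvest", year = 5, removed = 100), peat_mesic)
  pn <- p[p$nutrient == "N", ]
  expect_equal(nrow(pn), 6L)
  expect_equal(unique(pn$kg_ha), harvest_export_peat(100, "N"))
  expect_equal(pn$year, 5:10)

  # sub-xeric-or-poorer sites export for 4 years only
  p4 <- event_export_schedule(ev("clear_cut", year = 5, removed = 100), peat_xeric)
  expect_equal(sum(p4$nutrient == "N"), 4L)

  # DNM schedules are flagged particulate
  d <- event_export_schedule(ev("dnm"), peat_mesic)
  expect_true(all(d$particulate))
  expect_equal(d$kg_ha[d$nutrient == "N"][1], 4.00)

  # tending and regeneration are export-free
  expect_equal(nrow(event_export_schedule(ev("tending"), mineral)), 0L)
  expect_equal(nrow(event_export_schedule(ev("planting"), mineral)), 0L)

  # land-class mismatches are usage errors
  expect_error(event_export_schedule(ev("dnm"), mineral), "drained_peat")
  expect_error(event_export_schedule(ev("fertilization_peat_ash"), mineral),
               "drained_peat")
  expect_error(event_export_schedule(ev("fertilization_mineral_N"), peat_mesic),
               "mineral")
})

test_that("schedules are additive over disjoint events and linear in treated area", {
  peat <- make_stand(land_class = "drained_peat", fertility = "mesic",
                     species = "pine", years_since_dnm = 30, area = 4)
  ev <- function(year, removed) {
    list(event_type = "clear_cut", year = year, removed_volume_m3_ha = removed)
  }
  a <- event_export_schedule(ev(5, 120), peat)
  b <- event_export_schedule(ev(15, 120), peat)
  both_total <- sum(a$kg_ha) + sum(b$kg_ha)
  expect_equal(both_total, 2 * sum(a$kg_ha))
  # per-ha schedules are area-independent; ledger mass scales with area
  wide <- make_stand(land_class = "drained_peat", fertility = "mesic",
                     species = "pine", years_since_dnm = 30, area = 8)
  expect_equal(event_export_schedule(ev(5, 120), wide)$kg_ha, a$kg_ha)
})

test_that("coefficient overrides load from YAML and invalid schedules fail", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(dnm = list(N = as.list(c(5, rep(0, 9))))), path)
  co <- coefficients_from_yaml(path)
  expect_equal(coefficient_lookup("dnm", "N", 1, co), 5)
  expect_equal(coefficient_lookup("dnm", "P", 1, co), 0.288)  # untouched
  expect_error(export_coefficients(list(dnm = list(N = c(1, 2)))), "10 nonnegative")
})
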