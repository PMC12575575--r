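#' Surrogate stand-growth parameterization
#'
#' The simulator needs stand dynamics only as a driver for harvest timing and
#' for the evolving growing-stock volume that controls the drained-peat water
#' table. The surrogate is a diameter-cohort model: every cohort's annual
#' diameter increment is a base rate scaled down by stand basal area
#' (competition), scaled by site fertility, species and effective temperature
#' sum, and multiplied by the tree-breeding benefit of the regeneration
#' origin (planted 1.10, seeded 1.05). Stem volume per tree is the
#' two-parameter allometry `v(d) = vol_a * d^vol_b`. A constant background
#' ingrowth feeds the smallest cohort. The interface is pluggable: pass a
#' modified parameter list anywhere a `growth` argument is accepted.
#'
#' @param g0_cm_yr Base annual diameter increment (cm/yr) of a free-growing
#'   tree at the reference temperature sum.
#' @param ba_sens Competition sensitivity (per m2/ha of basal area); the
#'   increment is multiplied by `exp(-ba_sens * BA)`.
#' @param fertility_mult Named multipliers per fertility class.
#' @param species_mult Named multipliers per species.
#' @param origin_mult Named multipliers per regeneration origin; the 1.10 and
#'   1.05 values are the breeding benefits applied to the diameter-increment
#'   prediction for planted and seeded stands.
#' @param ts_ref Reference temperature sum (degree days); the increment
#'   scales with `climate$ts / ts_ref`.
#' @param ingrowth_stems_yr Background ingrowth (stems/ha/yr) entering at
#'   `ingrowth_d_cm`.
#' @param ingrowth_d_cm Diameter at which ingrowth enters (cm).
#' @param vol_a,vol_b Class volume function coefficients (m3 per stem for
#'   diameter in cm).
#' @param treatment_boost Multiplicative increment boost while a fertilization
#'   or ditch-maintenance growth response is active.
#' @param boost_years Duration of that response (years).
#'
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(g0_cm_yr = 0.6,
                          ba_sens = 0.035,
                          fertility_mult = c(herb_rich = 1.15, mesic = 1.0,
                                             sub_xeric = 0.85, xeric = 0.7),
                          species_mult = c(pine = 1.0, spruce = 0.95,
                                           birch = 1.05, mixed = 1.0),
                          origin_mult = c(planted = 1.10, seeded = 1.05,
                                          natural = 1.0),
                          ts_ref = 1200,
                          ingrowth_stems_yr = 15,
                          ingrowth_d_cm = 1.0,
                          vol_a = 2.5e-4,
                          vol_b = 2.3,
                          treatment_boost = 1.15,
                          boost_years = 10) {
  structure(
    list(
      g0_cm_yr = g0_cm_yr, ba_sens = ba_sens,
      fertility_mult = fertility_mult, species_mult = species_mult,
      origin_mult = origin_mult, ts_ref = ts_ref,
      ingrowth_stems_yr = ingrowth_stems_yr, ingrowth_d_cm = ingrowth_d_cm,
      vol_a = vol_a, vol_b = vol_b,
      treatment_boost = treatment_boost, boost_years = boost_years
    ),
    class = "growth_params"
  )
}

#' Climate constants for a simulation
#'
#' @param ts Effective temperature sum (degree days, > 5 C threshold).
#'   Default 1050, typical for the 64-65 degree N latitude band.
#' @param S Mean monthly summer (July-August) precipitation (mm). Default
#'   70 mm, consistent with roughly 524 mm annual precipitation in the region
#'   the synthetic catchment emulates.
#' @param LAT Northern latitude (degrees). Default 65.
#' @return A named list.
#' @export
climate_constants <- function(ts = 1050, S = 70, LAT = 65) {
  list(ts = ts, S = S, LAT = LAT)
}

# Annual diameter increment for each cohort of a stand. `boost` is TRUE while
# a fertilization/DNM growth response is active.
increment_cm <- function(ba, fertility, species, origin, growth, climate, boost = FALSE) {
  inc <- growth$g0_cm_yr *
    growth$fertility_mult[[fertility]] *
    growth$species_mult[[species]] *
    growth$origin_mult[[origin]] *
    (climate$ts / growth$ts_ref) *
    exp(-growth$ba_sens * ba)
  if (boost) inc <- inc * growth$treatment_boost
  inc
}

# One year of growth on the raw cohort state. `st` is a list with fields
# mid, stems, age, fertility, species, origin, boost_years_left, and the
# bookkeeping counters. Cohorts share one increment (the increment model has
# no size term), so relative origin effects are exact.
grow_one_year <- function(st, growth, climate) {
  if (any(st$stems < 0)) stop_usage("negative stems per hectare in stand state")
  if (length(st$mid)) {
    ba <- sum(st$stems * pi * (st$mid / 200)^2)
    inc <- increment_cm(ba, st$fertility, st$species, st$origin, growth, climate,
                        boost = st$boost_years_left > 0)
    st$mid <- st$mid + inc
  }
  if (growth$ingrowth_stems_yr > 0) {
    k <- which.min(st$mid)
    if (length(k) && st$mid[k] < growth$ingrowth_d_cm + 1) {
      st$stems[k] <- st$stems[k] + growth$ingrowth_stems_yr
    } else {
      st$mid <- c(st$mid, growth$ingrowth_d_cm)
      st$stems <- c(st$stems, growth$ingrowth_stems_yr)
    }
  }
  st$age <- st$age + 1
  if (!is.na(st$ysd)) st$ysd <- st$ysd + 1
  st$ysf <- st$ysf + 1
  if (st$boost_years_left > 0) st$boost_years_left <- st$boost_years_left - 1
  st
}

# Pack/unpack between the user-facing stand_compartment and the lean state
# list the simulation loop runs on.
as_state <- function(cmp) {
  list(
    id = cmp$id, area = cmp$area_ha, land_class = cmp$land_class,
    fertility = cmp$fertility, species = cmp$dominant_species,
    origin = cmp$origin,
    mid = cmp$diameter_classes$mid_cm, stems = cmp$diameter_classes$stems_ha,
    age = cmp$age_years, ditch = cmp$ditch_depth_cm,
    ysd = cmp$years_since_dnm, ysf = cmp$years_since_fertilization,
    dnm_pending = isTRUE(cmp$dnm_pending),
    fert_this_rotation = isTRUE(cmp$fert_this_rotation),
    boost_years_left = cmp$boost_years_left %||% 0
  )
}

state_to_compartment <- function(st, growth) {
  cmp <- compartment(
    id = st$id, area_ha = st$area, land_class = st$land_class,
    fertility = st$fertility, dominant_species = st$species,
    origin = st$origin,
    diameter_classes = data.frame(mid_cm = st$mid, stems_ha = st$stems),
    age_years = st$age, ditch_depth_cm = st$ditch,
    years_since_dnm = st$ysd, years_since_fertilization = st$ysf,
    growth = growth
  )
  cmp$dnm_pending <- st$dnm_pending
  cmp$fert_this_rotation <- st$fert_this_rotation
  cmp$boost_years_left <- st$boost_years_left
  cmp
}

#' Grow a compartment for a number of years
#'
#' Advances the diameter-cohort table with the surrogate growth model; no
#' management happens here. Volume, basal area and mean diameter are
#' recomputed from the advanced table.
#'
#' @param cmp A [compartment()].
#' @param years Number of years (> 0, integer).
#' @param climate Climate constants, see [climate_constants()].
#' @param growth Growth parameterization, see [growth_params()].
#' @return The grown compartment, with attribute `"annual_volumes"` holding
#'   the end-of-year volume (m3/ha) for each simulated year.
#' @export
#' @examples
#' cmp <- compartment("a", 2, "mineral", "mesic", "spruce", "natural",
#'                    data.frame(mid_cm = 15, stems_ha = 900), age_years = 40)
#' grown <- grow_stand(cmp, 10)
#' grown$volume_m3_ha > cmp$volume_m3_ha
grow_stand <- function(cmp, years, climate = climate_constants(),
                       growth = growth_params()) {
  if (!is.numeric(years) || years <= 0) stop_usage("years must be > 0")
  st <- as_state(cmp)
  vols <- numeric(years)
  for (y in seq_len(years)) {
    st <- grow_one_year(st, growth, climate)
    vols[y] <- sum(st$stems * growth$vol_a * st$mid^growth$vol_b)
  }
  out <- state_to_compartment(st, growth)
  attr(out, "annual_volumes") <- vols
  out
}
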