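#' Is a stand mature for final felling?
#'
#' A final felling is triggered when the mean diameter strictly exceeds the
#' recommended minimum; under the extended-rotation system the minimum is the
#' rotation-forestry threshold multiplied by `erp_diameter_multiplier`
#' (default 1.10).
#'
#' @param cmp A [compartment()].
#' @param rules A [management_rules()] object.
#' @param system `"RF"` or `"ERP"`.
#' @return Logical.
#' @export
check_final_felling <- function(cmp, rules = management_rules(),
                                system = c("RF", "ERP")) {
  system <- match.arg(system)
  thr <- felling_min_d(rules, cmp$dominant_species, cmp$fertility)
  if (system == "ERP") thr <- thr * rules$erp_diameter_multiplier
  cmp$mean_diameter_cm > thr
}

# Removal plan for an even-aged thinning. Half of the basal-area removal uses
# a uniform percentage across cohorts; the other half takes whole cohorts
# smallest-first ("below") or largest-first ("above"), with a fractional stem
# count in the boundary cohort. Returns stems removed per cohort.
thinning_removal <- function(mid, stems, remove_ba, mode) {
  ba_i <- stems * pi * (mid / 200)^2
  frac_u <- (remove_ba / 2) / sum(ba_i)
  rem <- stems * frac_u
  left_ba <- ba_i * (1 - frac_u)
  ord <- order(mid, decreasing = (mode == "above"))
  need <- remove_ba / 2
  for (k in ord) {
    if (need <= 0) break
    if (left_ba[k] <= 1e-12) next
    take_ba <- min(left_ba[k], need)
    rem[k] <- rem[k] + stems[k] * (1 - frac_u) * (take_ba / left_ba[k])
    need <- need - take_ba
  }
  pmin(rem, stems)
}

#' Apply a commercial thinning
#'
#' Thins the stand to the rule set's post-thinning basal area when the
#' thinning limit is exceeded. `mode = "below"` removes the directed half of
#' the basal-area reduction from the smallest cohorts (rotation forestry);
#' `mode = "above"` from the largest (extended rotation).
#'
#' @param cmp A [compartment()].
#' @param mode `"below"` or `"above"`.
#' @param rules A [management_rules()].
#' @param growth Growth parameterization (for removed-volume accounting).
#' @return List with the thinned `compartment` and `removed_volume_m3_ha`.
#'   If the thinning limit is not exceeded the stand is returned unchanged
#'   with zero removal (and a warning if the post-thinning target is not
#'   below the current basal area).
#' @export
apply_thinning <- function(cmp, mode = c("below", "above"),
                           rules = management_rules(),
                           growth = growth_params()) {
  mode <- match.arg(mode)
  ba <- cmp$basal_area_m2_ha
  if (ba <= rules$thinning_limit_ba) {
    return(list(compartment = cmp, removed_volume_m3_ha = 0))
  }
  if (rules$post_thinning_ba >= ba) {
    warning("post-thinning target is not below the current basal area; no thinning applied")
    return(list(compartment = cmp, removed_volume_m3_ha = 0))
  }
  mid <- cmp$diameter_classes$mid_cm
  stems <- cmp$diameter_classes$stems_ha
  rem <- thinning_removal(mid, stems, ba - rules$post_thinning_ba, mode)
  removed_v <- sum(rem * growth$vol_a * mid^growth$vol_b)
  cmp$diameter_classes$stems_ha <- pmax(stems - rem, 0)
  cmp <- refresh_summaries(cmp, growth)
  list(compartment = cmp, removed_volume_m3_ha = removed_v)
}

# Continuous-cover harvest threshold (m2/ha) as a function of mean diameter,
# fertility, temperature sum and discount rate. Fertile sites carry more
# basal area before a cut pays off.
ccf_threshold_ba <- function(rules, mean_d, fertility, ts, discount_rate = NULL) {
  rate <- discount_rate %||% rules$ccf_discount_rate
  fert_shift <- c(herb_rich = 1, mesic = 0, sub_xeric = -1, xeric = -2)[[fertility]]
  (rules$ccf_threshold_a + fert_shift + rules$ccf_threshold_b * mean_d) *
    sqrt(ts / rules$ccf_ts_ref) *
    (rate / 0.03)^rules$ccf_discount_exponent
}

#' Check and plan a continuous-cover harvest
#'
#' A cut is triggered when stand basal area exceeds a threshold that rises
#' with mean diameter and site fertility. The removal plan is a thinning from
#' above: per-cohort removal fractions increase with diameter
#' (`(d/max(d))^power`, scaled to meet the basal-area removal and capped).
#'
#' @param cmp A [compartment()].
#' @param rules A [management_rules()].
#' @param climate Climate constants (temperature sum enters the threshold).
#' @return List with `cut` (logical), `threshold_ba`, and (when cutting)
#'   `removal_fractions` per cohort and `remove_ba`.
#' @export
check_ccf_harvest <- function(cmp, rules = management_rules(),
                              climate = climate_constants()) {
  thr <- ccf_threshold_ba(rules, cmp$mean_diameter_cm, cmp$fertility, climate$ts)
  ba <- cmp$basal_area_m2_ha
  if (ba <= thr) {
    return(list(cut = FALSE, threshold_ba = thr))
  }
  mid <- cmp$diameter_classes$mid_cm
  stems <- cmp$diameter_classes$stems_ha
  ba_i <- stems * pi * (mid / 200)^2
  remove_ba <- ba - min(rules$ccf_residual_ba, thr)
  w <- (mid / max(mid))^rules$ccf_intensity_power
  lambda <- remove_ba / sum(w * ba_i)
  for (it in 1:40) {
    r <- pmin(lambda * w, rules$ccf_max_intensity)
    got <- sum(r * ba_i)
    if (abs(got - remove_ba) < 1e-10) break
    free <- lambda * w < rules$ccf_max_intensity
    if (!any(free)) break
    lambda <- lambda * (1 + (remove_ba - got) / sum(w[free] * ba_i[free] * lambda))
  }
  list(cut = TRUE, threshold_ba = thr, removal_fractions = r, remove_ba = remove_ba)
}

#' Is a stand eligible for fertilization?
#'
#' Mineral-soil nitrogen fertilization happens only in even-aged management
#' (RF or ERP), on pine-dominated xeric and spruce-dominated mesic sites,
#' inside the 23-33 cm / 15-40 m2/ha window, more than 10 years after the
#' previous fertilization, and at most once per rotation. Drained-peat
#' (wood-ash) fertilization happens under RF and CCF inside the 5-30 cm /
#' 10-40 m2/ha window, more than 50 years after the previous treatment.
#'
#' @param cmp A [compartment()].
#' @param rules A [management_rules()].
#' @param land_class `"mineral"` or `"drained_peat"`.
#' @param system Management system: `"RF"`, `"ERP"`, `"CCF"` or `"none"`.
#' @return Logical.
#' @export
check_fertilization <- function(cmp, rules = management_rules(),
                                land_class = cmp$land_class,
                                system = c("RF", "ERP", "CCF", "none")) {
  system <- match.arg(system)
  if (system == "none") return(FALSE)
  d <- cmp$mean_diameter_cm
  ba <- cmp$basal_area_m2_ha
  elapsed <- cmp$years_since_fertilization
  if (land_class == "mineral") {
    if (!system %in% c("RF", "ERP")) return(FALSE)
    if (isTRUE(cmp$fert_this_rotation)) return(FALSE)
    w <- rules$fert_mineral
    ok_site <- any(vapply(
      w$eligible,
      function(p) p[1] == cmp$fertility && p[2] == cmp$dominant_species,
      logical(1)
    ))
    ok_site && d >= w$d[1] && d <= w$d[2] && ba >= w$ba[1] && ba <= w$ba[2] &&
      elapsed > w$min_interval
  } else if (land_class == "drained_peat") {
    if (!system %in% c("RF", "CCF")) return(FALSE)
    w <- rules$fert_peat
    d >= w$d[1] && d <= w$d[2] && ba >= w$ba[1] && ba <= w$ba[2] &&
      elapsed > w$min_interval
  } else {
    FALSE
  }
}

#' Is a drained-peat stand eligible for ditch-network maintenance?
#'
#' DNM is tied to the rotation: it requires a pending post-final-felling
#' trigger (set when the stand was clear-cut, or passed explicitly via
#' `after_final_felling`), the regenerated stand inside the 5-30 cm /
#' 10-40 m2/ha window, at least 30 years since the previous DNM, and a
#' growing-stock volume of at most 150 m3/ha -- beyond that, stand
#' evapotranspiration keeps the water table low without ditch maintenance.
#' Continuous-cover stands never clear-cut, so the trigger never arms and
#' they receive no DNM.
#'
#' @param cmp A [compartment()]; must be on drained peat.
#' @param rules A [management_rules()].
#' @param after_final_felling Override for the stored post-felling trigger.
#' @return Logical.
#' @export
check_dnm <- function(cmp, rules = management_rules(),
                      after_final_felling = isTRUE(cmp$dnm_pending)) {
  if (cmp$land_class != "drained_peat") {
    stop_usage("check_dnm() applies only to drained_peat compartments")
  }
  w <- rules$dnm
  after_final_felling &&
    cmp$mean_diameter_cm >= w$d[1] && cmp$mean_diameter_cm <= w$d[2] &&
    cmp$basal_area_m2_ha >= w$ba[1] && cmp$basal_area_m2_ha <= w$ba[2] &&
    !is.na(cmp$years_since_dnm) && cmp$years_since_dnm >= w$min_elapsed &&
    cmp$volume_m3_ha <= w$max_volume
}

# Draw the regeneration outcome for a felled stand. Returns species, origin,
# event type of the establishment, and the initial cohort.
draw_regeneration <- function(fertility, rules) {
  rg <- rules$regeneration[[fertility]]
  species <- names(rg$probs)[
    findInterval(runif(1), cumsum(rg$probs), left.open = TRUE) + 1L
  ]
  method <- rg$method
  origin <- switch(method, planting = "planted", seeding = "seeded",
                   seed_tree = "natural")
  event <- switch(method, planting = "planting", seeding = "seeding",
                  seed_tree = NA_character_)
  list(
    species = species, origin = origin, establishment_event = event,
    stems = rules$regen_stems[[method]], d_cm = rules$regen_d_cm
  )
}

# Mid-period treatment evaluation: final felling, then thinning / CCF
# harvest, then fertilization, then DNM. Mutates the lean state and returns
# the emitted event rows. `mid_year` dates all events.
evaluate_treatments <- function(st, system, rules, growth, climate, mid_year) {
  events <- list()
  emit <- function(type, removed = 0, year = mid_year) {
    events[[length(events) + 1L]] <<- list(
      event_type = type, year = year, removed_volume_m3_ha = removed
    )
  }
  if (system == "none") return(list(state = st, events = events))

  s <- stand_summaries(st$mid, st$stems, growth)
  seed_tree_site <- st$fertility == "xeric" && st$species == "pine"

  if (system %in% c("RF", "ERP")) {
    thr <- felling_min_d(rules, st$species, st$fertility)
    if (system == "ERP") thr <- thr * rules$erp_diameter_multiplier
    if (s$mean_d > thr) {
      # final felling + immediate site preparation and regeneration
      emit(if (seed_tree_site) "seed_tree_felling" else "clear_cut", s$volume)
      rg <- draw_regeneration(st$fertility, rules)
      emit("site_preparation")
      if (!is.na(rg$establishment_event)) emit(rg$establishment_event)
      emit("tending", year = mid_year + 10)
      st$mid <- rg$d_cm
      st$stems <- rg$stems
      st$species <- rg$species
      st$origin <- rg$origin
      st$age <- 0
      st$fert_this_rotation <- FALSE
      if (st$land_class == "drained_peat") st$dnm_pending <- TRUE
      s <- stand_summaries(st$mid, st$stems, growth)
    } else if (s$ba > rules$thinning_limit_ba) {
      mode <- if (system == "ERP") "above" else "below"
      rem <- thinning_removal(st$mid, st$stems, s$ba - rules$post_thinning_ba, mode)
      emit(paste0("thinning_", mode),
           sum(rem * growth$vol_a * st$mid^growth$vol_b))
      st$stems <- pmax(st$stems - rem, 0)
      s <- stand_summaries(st$mid, st$stems, growth)
    }
  } else if (system == "CCF") {
    thr <- ccf_threshold_ba(rules, s$mean_d, st$fertility, climate$ts)
    if (s$ba > thr && length(st$mid)) {
      ba_i <- st$stems * pi * (st$mid / 200)^2
      remove_ba <- s$ba - min(rules$ccf_residual_ba, thr)
      w <- (st$mid / max(st$mid))^rules$ccf_intensity_power
      lambda <- remove_ba / sum(w * ba_i)
      r <- pmin(lambda * w, rules$ccf_max_intensity)
      for (it in 1:40) {
        got <- sum(r * ba_i)
        if (abs(got - remove_ba) < 1e-10) break
        free <- lambda * w < rules$ccf_max_intensity
        if (!any(free)) break
        lambda <- lambda * (1 + (remove_ba - got) / sum(w[free] * ba_i[free] * lambda))
        r <- pmin(lambda * w, rules$ccf_max_intensity)
      }
      rem <- st$stems * r
      emit("ccf_harvest", sum(rem * growth$vol_a * st$mid^growth$vol_b))
      st$stems <- pmax(st$stems - rem, 0)
      s <- stand_summaries(st$mid, st$stems, growth)
    }
  }

  # fertilization (on the post-harvest state)
  fert_ok <- local({
    d <- s$mean_d; ba <- s$ba
    if (st$land_class == "mineral" && system %in% c("RF", "ERP") &&
        !st$fert_this_rotation) {
      w <- rules$fert_mineral
      ok_site <- any(vapply(
        w$eligible, function(p) p[1] == st$fertility && p[2] == st$species,
        logical(1)
      ))
      ok_site && d >= w$d[1] && d <= w$d[2] && ba >= w$ba[1] && ba <= w$ba[2] &&
        st$ysf > w$min_interval
    } else if (st$land_class == "drained_peat" && system %in% c("RF", "CCF")) {
      w <- rules$fert_peat
      d >= w$d[1] && d <= w$d[2] && ba >= w$ba[1] && ba <= w$ba[2] &&
        st$ysf > w$min_interval
    } else FALSE
  })
  if (fert_ok) {
    if (st$land_class == "mineral") {
      emit("fertilization_mineral_N")
      st$fert_this_rotation <- TRUE
      st$boost_years_left <- growth$boost_years
    } else {
      emit("fertilization_peat_ash")  # maintains growth; no boost
    }
    st$ysf <- 0
  }

  # ditch-network maintenance (drained peat, post-felling trigger armed)
  if (st$land_class == "drained_peat" && st$dnm_pending) {
    w <- rules$dnm
    if (s$mean_d >= w$d[1] && s$mean_d <= w$d[2] &&
        s$ba >= w$ba[1] && s$ba <= w$ba[2] &&
        !is.na(st$ysd) && st$ysd >= w$min_elapsed &&
        s$volume <= w$max_volume) {
      emit("dnm")
      st$ysd <- 0
      st$dnm_pending <- FALSE
      st$boost_years_left <- growth$boost_years
    }
  }

  list(state = st, events = events)
}

events_to_tibble <- function(events, id, area) {
  if (!length(events)) {
    return(tibble::tibble(
      compartment_id = character(), event_type = character(),
      year = integer(), removed_volume_m3_ha = numeric(),
      treated_area_ha = numeric()
    ))
  }
  tibble::tibble(
    compartment_id = id,
    event_type = vapply(events, `[[`, character(1), "event_type"),
    year = as.integer(vapply(events, `[[`, numeric(1), "year")),
    removed_volume_m3_ha = vapply(events, `[[`, numeric(1), "removed_volume_m3_ha"),
    treated_area_ha = area
  )
}

#' Advance a compartment by one 10-year period
#'
#' Grows the stand for five years, evaluates treatments at the mid-period
#' year (final felling, then thinning or continuous-cover harvest, then
#' fertilization, then ditch-network maintenance; regeneration immediately
#' follows a clear-fell and tending is scheduled for the following period),
#' then grows five more years. All treatment events are dated to the
#' mid-period year `(period_index - 1) * 10 + 5`.
#'
#' @param cmp A [compartment()].
#' @param system `"RF"`, `"ERP"`, `"CCF"` or `"none"`.
#' @param rules A [management_rules()].
#' @param period_index 1-based period number.
#' @param climate Climate constants.
#' @param growth Growth parameterization.
#' @return List with `compartment`, `events` (tibble) and `annual_volumes`
#'   (end-of-year volume, m3/ha, for the 10 years of the period).
#' @export
step_period <- function(cmp, system = c("RF", "ERP", "CCF", "none"),
                        rules = management_rules(), period_index = 1,
                        climate = climate_constants(),
                        growth = growth_params()) {
  system <- match.arg(system)
  if (system == "ERP" && cmp$land_class == "drained_peat") {
    stop_usage("the extended-rotation system is defined for mineral soils only")
  }
  st <- as_state(cmp)
  mid_year <- (period_index - 1L) * 10L + 5L
  vols <- numeric(10)
  for (y in 1:5) {
    st <- grow_one_year(st, growth, climate)
    vols[y] <- sum(st$stems * growth$vol_a * st$mid^growth$vol_b)
  }
  tr <- evaluate_treatments(st, system, rules, growth, climate, mid_year)
  st <- tr$state
  vols[5] <- sum(st$stems * growth$vol_a * st$mid^growth$vol_b)
  for (y in 6:10) {
    st <- grow_one_year(st, growth, climate)
    vols[y] <- sum(st$stems * growth$vol_a * st$mid^growth$vol_b)
  }
  list(
    compartment = state_to_compartment(st, growth),
    events = events_to_tibble(tr$events, cmp$id, cmp$area_ha),
    annual_volumes = vols
  )
}
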