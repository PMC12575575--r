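#' Scenario specification
#'
#' One combination of a management system and a water-protection practice,
#' with the climate constants and horizon of the run. The extended-rotation
#' system is defined for mineral soils only; requesting it for a register
#' containing drained-peat forest is rejected at validation. One protection
#' practice at a time: structures are not combined.
#'
#' @param management `"RF"`, `"ERP"`, `"CCF"` or `"none"`.
#' @param protection `"none"`, `"ponds"`, `"dams"`, `"wetlands"` or
#'   `"riparian"`.
#' @param horizon_years Simulation horizon (default 50), divisible by
#'   `period_length`.
#' @param period_length Reporting/treatment period (default 10 years).
#' @param climate Climate constants, see [climate_constants()].
#' @param seed Random seed of the run (regeneration species draws).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(management = c("RF", "ERP", "CCF", "none"),
                          protection = c("none", "ponds", "dams", "wetlands",
                                         "riparian"),
                          horizon_years = 50, period_length = 10,
                          climate = climate_constants(), seed = 1L) {
  management <- match.arg(management)
  protection <- match.arg(protection)
  if (horizon_years %% period_length != 0) {
    stop_config("horizon_years must be divisible by period_length")
  }
  structure(
    list(management = management, protection = protection,
         horizon_years = as.integer(horizon_years),
         period_length = as.integer(period_length),
         climate = climate, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

# Simulate all compartments of a register over the horizon; returns the
# in-simulation events and the annual end-of-year volume matrix for
# drained-peat compartments. Treatments run at years == 5 (mod 10).
simulate_register <- function(register, spec, rules, growth) {
  H <- spec$horizon_years
  cmp <- register$compartments
  sim <- which(cmp$land_class %in% c("mineral", "drained_peat"))
  drained <- which(cmp$land_class == "drained_peat")
  vol <- matrix(0, nrow = length(drained), ncol = H,
                dimnames = list(cmp$id[drained], NULL))
  vrow <- match(sim, drained)

  ev_id <- character(0); ev_type <- character(0); ev_year <- integer(0)
  ev_removed <- numeric(0); ev_area <- numeric(0)

  va <- growth$vol_a; vb <- growth$vol_b
  for (k in seq_along(sim)) {
    i <- sim[k]
    st <- list(
      id = cmp$id[i], area = cmp$area_ha[i], land_class = cmp$land_class[i],
      fertility = cmp$fertility[i], species = cmp$dominant_species[i],
      origin = cmp$origin[i],
      mid = cmp$diameter_classes[[i]]$mid_cm,
      stems = cmp$diameter_classes[[i]]$stems_ha,
      age = cmp$age_years[i], ditch = cmp$ditch_depth_cm[i],
      ysd = cmp$years_since_dnm[i],
      ysf = cmp$years_since_fertilization[i],
      dnm_pending = FALSE, fert_this_rotation = FALSE, boost_years_left = 0
    )
    track <- !is.na(vrow[k])
    for (y in seq_len(H)) {
      st <- grow_one_year(st, growth, spec$climate)
      if (y %% 10L == 5L && spec$management != "none") {
        tr <- evaluate_treatments(st, spec$management, rules, growth,
                                  spec$climate, mid_year = y)
        st <- tr$state
        for (e in tr$events) {
          ev_id <- c(ev_id, st$id); ev_type <- c(ev_type, e$event_type)
          ev_year <- c(ev_year, as.integer(e$year))
          ev_removed <- c(ev_removed, e$removed_volume_m3_ha)
          ev_area <- c(ev_area, st$area)
        }
      }
      if (track) vol[vrow[k], y] <- sum(st$stems * va * st$mid^vb)
    }
  }
  list(
    events = tibble::tibble(
      compartment_id = ev_id, event_type = ev_type, year = ev_year,
      removed_volume_m3_ha = ev_removed, treated_area_ha = ev_area
    ),
    volumes = vol
  )
}

# Build ledger rows for all operation-induced exports (vectorized across
# events). Pre-simulation events contribute the in-horizon tail of their
# schedules.
operation_ledger <- function(events, register, coefficients, params, H) {
  cmp <- register$compartments
  idx <- match(events$compartment_id, cmp$id)
  acc <- list(); n_acc <- 0L

  add <- function(i, years, nutrient, kg_ha, source, particulate) {
    keep <- years >= 1 & years <= H & kg_ha > 0
    if (!any(keep)) return(invisible())
    n_acc <<- n_acc + 1L
    acc[[n_acc]] <<- list(
      id = events$compartment_id[i], lc = cmp$land_class[idx[i]],
      fert = cmp$fertility[idx[i]], area = events$treated_area_ha[i],
      years = as.integer(years[keep]), nutrient = nutrient,
      kg_ha = kg_ha[keep], source = source, particulate = particulate
    )
  }

  coef_vec <- function(op, nu) {
    coefficients$kg_ha_yr[coefficients$operation == op & coefficients$nutrient == nu]
  }
  cc_n <- coef_vec("clearcut_mineral", "N"); cc_p <- coef_vec("clearcut_mineral", "P")
  dnm_n <- coef_vec("dnm", "N"); dnm_p <- coef_vec("dnm", "P")
  fm_n <- coef_vec("fert_mineral", "N")
  fp_p <- coef_vec("fert_peat", "P")

  for (i in seq_len(nrow(events))) {
    type <- events$event_type[i]
    lc <- cmp$land_class[idx[i]]
    y0 <- events$year[i]
    if (lc == "mineral") {
      if (type %in% c("clear_cut", "seed_tree_felling")) {
        add(i, y0 + 0:9, "N", cc_n, "harvest", FALSE)
        add(i, y0 + 0:9, "P", cc_p, "harvest", FALSE)
      } else if (type == "fertilization_mineral_N") {
        add(i, y0 + 0:9, "N", fm_n, "fertilization", FALSE)
      }
    } else if (lc == "drained_peat") {
      if (type %in% HARVEST_EVENTS && events$removed_volume_m3_ha[i] > 0) {
        dur <- harvest_duration(cmp$fertility[idx[i]], params)
        v <- events$removed_volume_m3_ha[i]
        add(i, y0 + seq_len(dur) - 1L, "N",
            rep(harvest_export_peat(v, "N", params), dur), "harvest", FALSE)
        add(i, y0 + seq_len(dur) - 1L, "P",
            rep(harvest_export_peat(v, "P", params), dur), "harvest", FALSE)
      } else if (type == "dnm") {
        add(i, y0 + 0:9, "N", dnm_n, "dnm", TRUE)
        add(i, y0 + 0:9, "P", dnm_p, "dnm", TRUE)
      } else if (type == "fertilization_peat_ash") {
        add(i, y0 + 0:9, "P", fp_p, "fertilization", FALSE)
      }
    }
  }
  lens <- vapply(acc, function(a) length(a$years), integer(1))
  tibble::tibble(
    compartment_id = rep(vapply(acc, `[[`, character(1), "id"), lens),
    land_class = rep(vapply(acc, `[[`, character(1), "lc"), lens),
    fertility = rep(vapply(acc, `[[`, character(1), "fert"), lens),
    area_ha = rep(vapply(acc, `[[`, numeric(1), "area"), lens),
    year = unlist(lapply(acc, `[[`, "years"), use.names = FALSE) %||% integer(0),
    source = rep(vapply(acc, `[[`, character(1), "source"), lens),
    nutrient = rep(vapply(acc, `[[`, character(1), "nutrient"), lens),
    kg_ha = unlist(lapply(acc, `[[`, "kg_ha"), use.names = FALSE) %||% numeric(0),
    particulate = rep(vapply(acc, `[[`, logical(1), "particulate"), lens)
  )
}

# Annual legacy (peat-mineralization) exports for drained-peat compartments
# from the volume trajectory; fully vectorized.
legacy_ledger <- function(volumes, register, spec, response) {
  if (!nrow(volumes)) {
    return(tibble::tibble(
      compartment_id = character(), land_class = character(),
      fertility = character(), area_ha = numeric(), year = integer(),
      source = character(), nutrient = character(), kg_ha = numeric(),
      particulate = logical()
    ))
  }
  cmp <- register$compartments
  i <- match(rownames(volumes), cmp$id)
  H <- ncol(volumes)
  wtl <- compute_wtl(
    V = as.vector(volumes),
    S = spec$climate$S,
    D = rep(cmp$ditch_depth_cm[i], H),
    LAT = spec$climate$LAT
  )
  fert <- rep(cmp$fertility[i], H)
  exp_np <- legacy_export(wtl, fert, response)
  base <- tibble::tibble(
    compartment_id = rep(cmp$id[i], H),
    land_class = "drained_peat",
    fertility = fert,
    area_ha = rep(cmp$area_ha[i], H),
    year = rep(seq_len(H), each = nrow(volumes)),
    source = "legacy",
    particulate = FALSE
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(base, nutrient = "N", kg_ha = exp_np$N),
    dplyr::mutate(base, nutrient = "P", kg_ha = exp_np$P)
  )
  out[out$kg_ha > 0, c("compartment_id", "land_class", "fertility", "area_ha",
                       "year", "source", "nutrient", "kg_ha", "particulate")]
}

#' Run one management x protection scenario over a register
#'
#' Steps every mineral and drained-peat compartment through the horizon
#' (growth every year, treatments at mid-period under the chosen system),
#' converts the emitted events -- plus any pre-simulation event history in
#' the register -- into annual export increments, adds the annual
#' water-table-driven legacy exports of drained peatlands, applies the
#' water-protection practice, and assembles the export ledger. Under
#' `management = "none"` stands still grow (the legacy export depends on the
#' evolving volume) but no operations happen.
#'
#' @param register A `stand_register`.
#' @param spec A [scenario_spec()].
#' @param rules A [management_rules()].
#' @param models Named list of [retention_model()]s.
#' @param growth A [growth_params()].
#' @param response A [legacy_response()].
#' @param coefficients An [export_coefficients()] table.
#' @return A list of class `scenario_result` with:
#'   * `ledger`: tibble (compartment, year, source, nutrient, kg_ha, kg,
#'     particulate, retained_kg), forestry-induced exports only;
#'   * `harvest_series`: mean annual harvested volume (m3/ha/yr) per land
#'     class and period;
#'   * `events`: all dated management events of the run;
#'   * `spec`, and the register's per-class areas as attribute
#'     `class_areas`.
#' @export
run_scenario <- function(register, spec = scenario_spec(), rules = management_rules(),
                         models = default_protection_models(),
                         growth = growth_params(),
                         response = legacy_response(),
                         coefficients = export_coefficients()) {
  stopifnot(inherits(register, "stand_register"), inherits(spec, "scenario_spec"))
  if (spec$management == "ERP" &&
      any(register$compartments$land_class == "drained_peat")) {
    stop_usage("the ERP system is not defined for drained peatland forests; ",
               "subset the register to mineral compartments first")
  }
  set.seed(spec$seed)
  H <- spec$horizon_years
  sim <- simulate_register(register, spec, rules, growth)
  events <- dplyr::bind_rows(register$events, sim$events)
  events <- events[events$year <= H, ]

  params <- harvest_export_params()
  ledger <- dplyr::bind_rows(
    operation_ledger(events, register, coefficients, params, H),
    legacy_ledger(sim$volumes, register, spec, response)
  )
  ledger$kg <- ledger$kg_ha * ledger$area_ha
  ledger$retained_kg <- 0
  class_areas <- tapply(register$compartments$area_ha,
                        register$compartments$land_class, sum)
  attr(ledger, "class_areas") <- class_areas
  ledger <- apply_protection(ledger, spec$protection, models)
  attr(ledger, "class_areas") <- class_areas

  in_h <- events$year >= 1 & events$year <= H
  harvests <- events[in_h & events$event_type %in% HARVEST_EVENTS &
                       events$removed_volume_m3_ha > 0, ]
  cmp <- register$compartments
  harvests$land_class <- cmp$land_class[match(harvests$compartment_id, cmp$id)]
  harvests$period <- (harvests$year - 1L) %/% spec$period_length + 1L
  grid <- expand.grid(
    land_class = intersect(c("mineral", "drained_peat"), names(class_areas)),
    period = seq_len(H %/% spec$period_length), stringsAsFactors = FALSE
  )
  harvest_series <- tibble::as_tibble(grid)
  harvest_series$harvest_m3_ha_yr <- mapply(function(lc, p) {
    h <- harvests[harvests$land_class == lc & harvests$period == p, ]
    sum(h$removed_volume_m3_ha * h$treated_area_ha) /
      (class_areas[[lc]] * spec$period_length)
  }, harvest_series$land_class, harvest_series$period)

  structure(
    list(ledger = ledger, harvest_series = harvest_series, events = events,
         spec = spec, class_areas = class_areas),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  tot <- dplyr::summarise(
    dplyr::group_by(x$ledger, .data$nutrient),
    delivered_kg = sum(.data$kg - .data$retained_kg)
  )
  cat(sprintf("<scenario_result> %s + %s, %d years\n",
              x$spec$management, x$spec$protection, x$spec$horizon_years))
  for (j in seq_len(nrow(tot))) {
    cat(sprintf("  delivered %s: %.0f kg\n", tot$nutrient[j], tot$delivered_kg[j]))
  }
  invisible(x)
}

#' Accumulated per-hectare export time series
#'
#' Cumulative delivered (generated minus retained) export of one nutrient
#' from one land class, per hectare of that class's total area.
#'
#' @param ledger A scenario ledger (or a `scenario_result`).
#' @param land_class `"mineral"` or `"drained_peat"`.
#' @param nutrient `"N"` or `"P"`.
#' @param horizon_years Length of the series; defaults to the ledger's last
#'   year.
#' @param class_area_ha Area (ha) used for the per-hectare scaling; defaults
#'   to the register class area recorded on the ledger.
#' @return Tibble with `year` and nondecreasing `cumulative_kg_ha`.
#' @export
accumulate_exports <- function(ledger, land_class, nutrient,
                               horizon_years = NULL, class_area_ha = NULL) {
  if (inherits(ledger, "scenario_result")) ledger <- ledger$ledger
  class_area_ha <- class_area_ha %||% attr(ledger, "class_areas")[[land_class]]
  if (is.null(class_area_ha) || is.na(class_area_ha)) {
    stop_usage("class_area_ha not available; pass it explicitly")
  }
  horizon_years <- horizon_years %||% max(ledger$year, 1L)
  sel <- ledger$land_class == land_class & ledger$nutrient == nutrient
  annual <- numeric(horizon_years)
  if (any(sel)) {
    delivered <- (ledger$kg - ledger$retained_kg)[sel]
    agg <- tapply(delivered, ledger$year[sel], sum)
    annual[as.integer(names(agg))] <- agg
  }
  tibble::tibble(
    year = seq_len(horizon_years),
    cumulative_kg_ha = cumsum(annual) / class_area_ha
  )
}

#' Harvest-volume versus export relation
#'
#' One row per land class and period: the mean annual harvested volume and
#' the mean annual delivered N and P export, the scatter behind
#' harvest-vs-export comparisons of management systems.
#'
#' @param result A `scenario_result`.
#' @return Tibble with `land_class`, `period`, `harvest_m3_ha_yr`,
#'   `N_kg_ha_yr`, `P_kg_ha_yr`.
#' @export
harvest_export_relation <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  lg <- result$ledger
  pl <- result$spec$period_length
  out <- result$harvest_series
  out$N_kg_ha_yr <- NA_real_
  out$P_kg_ha_yr <- NA_real_
  for (j in seq_len(nrow(out))) {
    lc <- out$land_class[j]; p <- out$period[j]
    sel <- lg$land_class == lc & (lg$year - 1L) %/% pl + 1L == p
    area <- result$class_areas[[lc]]
    for (nu in c("N", "P")) {
      s <- sel & lg$nutrient == nu
      out[[paste0(nu, "_kg_ha_yr")]][j] <-
        sum((lg$kg - lg$retained_kg)[s]) / (area * pl)
    }
  }
  out
}

#' Tidy period-level report of a scenario
#'
#' @param result A `scenario_result`.
#' @param scenario_name Label stored in the `scenario` column.
#' @return Tibble `scenario, land_class, period, nutrient, source,
#'   kg_per_ha_yr, cumulative_kg_per_ha`.
#' @export
scenario_report <- function(result, scenario_name = paste(result$spec$management,
                                                          result$spec$protection,
                                                          sep = "+")) {
  lg <- result$ledger
  pl <- result$spec$period_length
  lg$period <- (lg$year - 1L) %/% pl + 1L
  lg$delivered <- lg$kg - lg$retained_kg
  agg <- dplyr::summarise(
    dplyr::group_by(lg, .data$land_class, .data$period, .data$nutrient, .data$source),
    kg = sum(.data$delivered), .groups = "drop"
  )
  agg$kg_per_ha_yr <- agg$kg /
    (unname(unlist(result$class_areas[agg$land_class])) * pl)
  agg <- dplyr::arrange(agg, .data$land_class, .data$nutrient, .data$source,
                        .data$period)
  agg <- dplyr::mutate(
    dplyr::group_by(agg, .data$land_class, .data$nutrient, .data$source),
    cumulative_kg_per_ha = cumsum(.data$kg) /
      unname(unlist(result$class_areas[.data$land_class]))
  )
  agg <- dplyr::ungroup(agg)
  tibble::tibble(
    scenario = scenario_name, land_class = agg$land_class,
    period = agg$period, nutrient = agg$nutrient, source = agg$source,
    kg_per_ha_yr = agg$kg_per_ha_yr,
    cumulative_kg_per_ha = agg$cumulative_kg_per_ha
  )
}
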