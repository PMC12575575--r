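#' Export-coefficient table for forestry operations
#'
#' Annual N and P export coefficients (kg/ha/yr) by years since treatment
#' (1-10) for ditch-network maintenance on drained peatlands, fertilization
#' of mineral-soil and drained-peatland forests, and clear-cutting of
#' mineral-soil forests. Partial harvests on mineral soils and P
#' fertilization of mineral soils are assumed not to increase exports (all
#' zero), and drained peatlands are not fertilized with N. The DNM columns
#' describe nutrients adhered to suspended solids (particulate); the 1.43
#' back-correction for water-protection structures is already embedded in
#' the values and is not re-applied. Beyond year 10 every coefficient is
#' zero.
#'
#' @param overrides Optional nested list `operation -> nutrient -> numeric(10)`
#'   replacing individual schedules.
#' @return A tibble with columns `operation` (`dnm`, `fert_mineral`,
#'   `fert_peat`, `clearcut_mineral`), `nutrient` (`N`, `P`), `year` (1-10)
#'   and `kg_ha_yr`, of class `export_coefficients`.
#' @export
export_coefficients <- function(overrides = NULL) {
  sched <- list(
    dnm = list(
      N = c(4.00, 1.33, 1.07, 0.80, 0.67, 0.53, 0.40, 0.27, 0.13, 0.07),
      P = c(0.288, 0.096, 0.077, 0.058, 0.048, 0.038, 0.029, 0.019, 0.010, 0.005)
    ),
    fert_mineral = list(
      N = c(12, 3, 0, 0, 0, 0, 0, 0, 0, 0),
      P = rep(0, 10)
    ),
    fert_peat = list(
      N = rep(0, 10),
      P = c(0.27, 0.27, 0.27, 0.27, 0.27, 0, 0, 0, 0, 0)
    ),
    clearcut_mineral = list(
      N = c(1.43, 1.42, 1.61, 1.41, 1.21, 1.01, 0.81, 0.60, 0.40, 0.20),
      P = c(0.20, 0.21, 0.20, 0.18, 0.15, 0.13, 0.10, 0.08, 0.05, 0.03)
    )
  )
  sched <- merge_config(sched, overrides)
  tab <- do.call(rbind, lapply(names(sched), function(op) {
    do.call(rbind, lapply(names(sched[[op]]), function(nu) {
      v <- sched[[op]][[nu]]
      if (length(v) != 10 || any(v < 0)) {
        stop_config("coefficient schedules must be 10 nonnegative values (",
                    op, "/", nu, ")")
      }
      data.frame(operation = op, nutrient = nu, year = 1:10, kg_ha_yr = v)
    }))
  }))
  structure(tibble::as_tibble(tab), class = c("export_coefficients", class(tibble::tibble())))
}

#' Read export-coefficient overrides from YAML
#' @param path YAML file with blocks like `dnm: {N: [...], P: [...]}`.
#' @return An `export_coefficients` tibble.
#' @export
coefficients_from_yaml <- function(path) {
  export_coefficients(yaml::read_yaml(path))
}

#' Look up one export coefficient
#'
#' @param operation One of `"dnm"`, `"fert_mineral"`, `"fert_peat"`,
#'   `"clearcut_mineral"`.
#' @param nutrient `"N"` or `"P"`.
#' @param years_since_treatment Integer years (>= 1, vectorized); year 1 is
#'   the treatment year itself. Years beyond 10 return 0.
#' @param coefficients Table from [export_coefficients()].
#' @return Coefficient(s) in kg/ha/yr.
#' @export
#' @examples
#' coefficient_lookup("dnm", "N", 1)   # 4.00
#' coefficient_lookup("dnm", "N", 11)  # 0
coefficient_lookup <- function(operation, nutrient, years_since_treatment,
                               coefficients = export_coefficients()) {
  if (!operation %in% unique(coefficients$operation)) {
    stop_config("unknown operation '", operation, "'")
  }
  if (!nutrient %in% c("N", "P")) stop_config("nutrient must be 'N' or 'P'")
  y <- years_since_treatment
  if (any(y < 1) || any(y != floor(y))) {
    stop_usage("years_since_treatment must be integers >= 1")
  }
  sched <- coefficients$kg_ha_yr[
    coefficients$operation == operation & coefficients$nutrient == nutrient
  ]
  out <- numeric(length(y))
  inside <- y <= 10
  out[inside] <- sched[y[inside]]
  out
}

#' Logistic harvest-export parameters for drained peatlands
#'
#' The annual N and P exports induced by harvesting a drained peatland stand
#' follow logistic curves in the harvested stem volume:
#' \deqn{N_{harvest} = 10 / (1 + e^{-(-3.3375 + 0.0164 V_{cut})})}
#' \deqn{P_{harvest} = 1.3 / (1 + e^{-(-5.1772 + 0.0209 V_{cut})})}
#' The export lasts 4 years on low-productive sites (sub-xeric or poorer)
#' and 6 years on fertile sites (mesic or better), at a constant annual
#' level.
#'
#' @param n_asymptote,n_intercept,n_slope N-curve parameters.
#' @param p_asymptote,p_intercept,p_slope P-curve parameters.
#' @param duration_fertile,duration_poor Export duration (years) on fertile
#'   (mesic or better) and low-productive sites.
#' @return A list of class `harvest_export_params`.
#' @export
harvest_export_params <- function(n_asymptote = 10, n_intercept = -3.3375,
                                  n_slope = 0.0164,
                                  p_asymptote = 1.3, p_intercept = -5.1772,
                                  p_slope = 0.0209,
                                  duration_fertile = 6, duration_poor = 4) {
  stopifnot(n_asymptote > 0, p_asymptote > 0, n_slope > 0, p_slope > 0)
  structure(
    list(n_asymptote = n_asymptote, n_intercept = n_intercept, n_slope = n_slope,
         p_asymptote = p_asymptote, p_intercept = p_intercept, p_slope = p_slope,
         duration_fertile = duration_fertile, duration_poor = duration_poor),
    class = "harvest_export_params"
  )
}

harvest_duration <- function(fertility, params = harvest_export_params()) {
  ifelse(fertility %in% c("mesic", "herb_rich"),
         params$duration_fertile, params$duration_poor)
}

#' Annual harvest-induced nutrient export from a drained peatland
#'
#' @param v_cut_m3_ha Harvested stem volume (m3/ha), >= 0. Vectorized.
#' @param nutrient `"N"` or `"P"`.
#' @param params A [harvest_export_params()].
#' @return Export in kg/ha/yr, strictly increasing in `v_cut_m3_ha` and
#'   bounded by the asymptote.
#' @export
#' @examples
#' harvest_export_peat(203.5, "N")  # close to the 5.0 kg/ha/yr midpoint
harvest_export_peat <- function(v_cut_m3_ha, nutrient = c("N", "P"),
                                params = harvest_export_params()) {
  nutrient <- match.arg(nutrient)
  if (any(v_cut_m3_ha < 0)) stop_domain("v_cut_m3_ha must be >= 0")
  if (nutrient == "N") {
    params$n_asymptote / (1 + exp(-(params$n_intercept + params$n_slope * v_cut_m3_ha)))
  } else {
    params$p_asymptote / (1 + exp(-(params$p_intercept + params$p_slope * v_cut_m3_ha)))
  }
}

#' Annual export schedule for one management event
#'
#' Converts a dated management event on a compartment into per-hectare annual
#' N and P export increments. Schedule year 1 falls in the calendar year of
#' the event (a mid-period treatment therefore contributes five in-period
#' years). Rules:
#' * mineral clear-cut or seed-tree felling: the 10-year clear-cut
#'   coefficient schedules;
#' * mineral partial harvests (thinnings, continuous-cover harvests): no
#'   export;
#' * mineral N fertilization: the 2-year N schedule;
#' * drained-peat harvest of any kind with removal: the logistic
#'   volume-response level, constant for 4 or 6 years depending on site
#'   fertility;
#' * drained-peat ash fertilization: the 5-year P schedule;
#' * DNM: the 10-year particulate schedules (flagged `particulate`).
#' Site preparation, planting, seeding and tending carry no export.
#'
#' @param event A one-row data frame (or list) with `event_type`, `year` and
#'   `removed_volume_m3_ha`.
#' @param cmp A [compartment()] (supplies land class and fertility).
#' @param coefficients Table from [export_coefficients()].
#' @param params A [harvest_export_params()].
#' @return Tibble with columns `year` (calendar year), `nutrient`, `kg_ha`,
#'   `source` (`harvest`, `dnm` or `fertilization`) and `particulate`.
#'   Zero-valued rows are dropped.
#' @export
event_export_schedule <- function(event, cmp,
                                  coefficients = export_coefficients(),
                                  params = harvest_export_params()) {
  type <- event$event_type
  match_token(type, EVENT_TYPES, "event_type")
  lc <- cmp$land_class
  if (!lc %in% c("mineral", "drained_peat")) {
    stop_usage("events are only defined for mineral and drained_peat compartments")
  }
  if (type == "dnm" && lc != "drained_peat") {
    stop_usage("dnm events apply to drained_peat compartments only")
  }
  if (type == "fertilization_mineral_N" && lc != "mineral") {
    stop_usage("mineral N fertilization applies to mineral compartments only")
  }
  if (type == "fertilization_peat_ash" && lc != "drained_peat") {
    stop_usage("ash fertilization applies to drained_peat compartments only")
  }

  empty <- tibble::tibble(
    year = integer(), nutrient = character(), kg_ha = numeric(),
    source = character(), particulate = logical()
  )
  sched <- function(op, source, particulate = FALSE) {
    n <- coefficient_lookup(op, "N", 1:10, coefficients)
    p <- coefficient_lookup(op, "P", 1:10, coefficients)
    tibble::tibble(
      year = as.integer(event$year + rep(0:9, 2L)),
      nutrient = rep(c("N", "P"), each = 10L),
      kg_ha = c(n, p), source = source, particulate = particulate
    )
  }
  out <- if (lc == "mineral") {
    switch(type,
      clear_cut = ,
      seed_tree_felling = sched("clearcut_mineral", "harvest"),
      fertilization_mineral_N = sched("fert_mineral", "fertilization"),
      empty
    )
  } else {
    if (type %in% HARVEST_EVENTS) {
      v <- event$removed_volume_m3_ha
      if (v > 0) {
        dur <- harvest_duration(cmp$fertility, params)
        tibble::tibble(
          year = as.integer(event$year + rep(seq_len(dur) - 1L, 2L)),
          nutrient = rep(c("N", "P"), each = dur),
          kg_ha = c(rep(harvest_export_peat(v, "N", params), dur),
                    rep(harvest_export_peat(v, "P", params), dur)),
          source = "harvest", particulate = FALSE
        )
      } else empty
    } else {
      switch(type,
        dnm = sched("dnm", "dnm", particulate = TRUE),
        fertilization_peat_ash = sched("fert_peat", "fertilization"),
        empty
      )
    }
  }
  out[out$kg_ha > 0, ]
}
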