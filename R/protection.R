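#' Retention model for a water-protection structure
#'
#' One parameterization of a load-dependent reduction curve. Four structures
#' are modelled:
#' * `pond` (sedimentation pond) and `dam` (peak-runoff-control dam): act
#'   only on particulate nutrient loads from ditch-network maintenance. The
#'   fraction retained saturates with the incoming load,
#'   `max_fraction * (1 - exp(-(L - cutoff)/K))` above a low-load cutoff
#'   below which retention is zero (never negative). The pond peak is 40% of
#'   the load above the pond; the dam peak is not separately reported and
#'   defaults to the pond value (flagged configuration, not data).
#' * `wetland` (natural wetland buffer): retains forestry-induced exports of
#'   drained peatlands. The retained fraction is logistic in the
#'   forestry-induced load (load above the buffer minus the non-forestry
#'   background, N 1.3 and P 0.025 kg/ha/yr), approaching `max_fraction`
#'   at high loads; behaviour below 0.6 kg N/ha/yr is an extrapolation
#'   beyond the source data.
#' * `riparian` (riparian buffer zone): a flat, coverage-based fraction:
#'   12% retention at the 3% base coverage, plus 5 percentage points per
#'   doubling of coverage.
#'
#' @param structure `"pond"`, `"dam"`, `"wetland"` or `"riparian"`.
#' @param ... Parameter overrides (see the defaults in the function body):
#'   ponds/dams take `max_fraction`, `cutoff_kg_ha_yr`, `k_kg_ha_yr`;
#'   wetlands `max_fraction`, `l50_n`, `scale_n`, `l50_p`, `scale_p`,
#'   `background_n`, `background_p`; riparian `base_coverage_pct`,
#'   `base_retention_pct`, `doubling_increment_pct`.
#' @return A list of class `retention_model`.
#' @export
retention_model <- function(structure = c("pond", "dam", "wetland", "riparian"),
                            ...) {
  structure_ <- match.arg(structure)
  defaults <- switch(structure_,
    pond = list(max_fraction = 0.40, cutoff_kg_ha_yr = 0.5, k_kg_ha_yr = 2),
    dam = list(max_fraction = 0.40, cutoff_kg_ha_yr = 0.5, k_kg_ha_yr = 2),
    wetland = list(max_fraction = 0.9,
                   l50_n = 0.3, scale_n = 0.15,
                   l50_p = 0.02, scale_p = 0.01,
                   background_n = 1.3, background_p = 0.025),
    riparian = list(base_coverage_pct = 3, base_retention_pct = 12,
                    doubling_increment_pct = 5)
  )
  pars <- merge_config(defaults, list(...))
  if (!is.null(pars$max_fraction) &&
      (pars$max_fraction < 0 || pars$max_fraction >= 1)) {
    stop_config("max_fraction must be in [0, 1)")
  }
  structure(c(list(structure = structure_), pars), class = "retention_model")
}

#' Default retention models for all four structures
#' @return Named list of [retention_model()]s.
#' @export
default_protection_models <- function() {
  list(
    pond = retention_model("pond"),
    dam = retention_model("dam"),
    wetland = retention_model("wetland"),
    riparian = retention_model("riparian")
  )
}

#' Read retention models from a YAML file
#' @param path YAML file with one block per structure name.
#' @return Named list of [retention_model()]s.
#' @export
protection_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  models <- default_protection_models()
  for (nm in names(raw)) {
    if (!nm %in% names(models)) stop_config("unknown protection structure '", nm, "'")
    models[[nm]] <- do.call(retention_model, c(list(structure = nm), raw[[nm]]))
  }
  models
}

saturating_fraction <- function(load, params) {
  excess <- pmax(0, load - params$cutoff_kg_ha_yr)
  params$max_fraction * (1 - exp(-excess / params$k_kg_ha_yr))
}

#' Sedimentation-pond retention fraction
#'
#' Fraction of the (particulate) load above the pond that is retained: zero
#' at and below the low-load cutoff, monotone nondecreasing, approaching the
#' 40% peak at high loads.
#'
#' @param load_above_kg_ha_yr Load above the structure (kg/ha/yr), >= 0.
#'   Vectorized.
#' @param params A `pond` [retention_model()].
#' @return Retention fraction in `[0, max_fraction]`.
#' @export
pond_retention <- function(load_above_kg_ha_yr,
                           params = retention_model("pond")) {
  if (any(load_above_kg_ha_yr < 0)) stop_domain("load must be >= 0")
  saturating_fraction(load_above_kg_ha_yr, params)
}

#' Peak-runoff-control dam retention fraction
#'
#' Same functional form as [pond_retention()] with the dam's own parameters;
#' the default peak mirrors the pond's 40% because no separate peak is
#' reported for dams.
#'
#' @inheritParams pond_retention
#' @param params A `dam` [retention_model()].
#' @export
dam_retention <- function(load_above_kg_ha_yr,
                          params = retention_model("dam")) {
  if (any(load_above_kg_ha_yr < 0)) stop_domain("load must be >= 0")
  saturating_fraction(load_above_kg_ha_yr, params)
}

wetland_fraction <- function(forestry_load, nutrient, params) {
  l50 <- if (nutrient == "N") params$l50_n else params$l50_p
  sc <- if (nutrient == "N") params$scale_n else params$scale_p
  params$max_fraction / (1 + exp(-(forestry_load - l50) / sc))
}

#' Wetland-buffer retention of forestry-induced exports
#'
#' The non-forestry background export (N 1.3, P 0.025 kg/ha/yr) is
#' subtracted from the load above the buffer; the retained mass is the
#' load-dependent fraction of the remaining forestry-induced load. Zero when
#' the load above does not exceed the background.
#'
#' @param load_above Total load above the buffer (kg/ha/yr), background
#'   included. Vectorized.
#' @param nutrient `"N"` or `"P"`.
#' @param params A `wetland` [retention_model()].
#' @return Retained mass (kg/ha/yr), never exceeding the forestry-induced
#'   load.
#' @export
wetland_retention <- function(load_above, nutrient = c("N", "P"),
                              params = retention_model("wetland")) {
  nutrient <- match.arg(nutrient)
  if (any(load_above < 0)) stop_domain("load must be >= 0")
  bg <- if (nutrient == "N") params$background_n else params$background_p
  forestry <- pmax(0, load_above - bg)
  wetland_fraction(forestry, nutrient, params) * forestry
}

#' Riparian buffer-zone retention fraction
#'
#' Buffer zones covering 3% of the catchment retain about 12% of
#' forestry-induced loading; doubling the coverage adds about 5 percentage
#' points. The fraction is
#' `(base_retention + increment * log2(coverage / base_coverage)) / 100`,
#' clipped to `[0, 1)`, and zero at zero coverage.
#'
#' @param coverage_percent Buffer coverage as % of the catchment area, >= 0.
#'   Vectorized.
#' @param params A `riparian` [retention_model()].
#' @return Retention fraction.
#' @export
#' @examples
#' riparian_retention(3)  # 0.12
#' riparian_retention(6)  # 0.17
riparian_retention <- function(coverage_percent,
                               params = retention_model("riparian")) {
  if (any(coverage_percent < 0)) stop_domain("coverage must be >= 0")
  out <- ifelse(
    coverage_percent == 0, 0,
    (params$base_retention_pct + params$doubling_increment_pct *
       log2(coverage_percent / params$base_coverage_pct)) / 100
  )
  pmin(pmax(out, 0), 1 - 1e-12)
}

#' Apply one water-protection practice to an export ledger
#'
#' Fills the `retained_kg` column of a ledger according to the chosen
#' practice:
#' * `ponds` / `dams`: reduce only particulate DNM entries of drained-peat
#'   compartments, with the fraction evaluated on the compartment's summed
#'   DNM load (kg/ha/yr) in that year;
#' * `wetlands`: reduce all forestry-induced entries of drained-peat
#'   compartments, with the fraction evaluated on the compartment's total
#'   forestry-induced load in that year;
#' * `riparian`: reduce all forestry-induced entries of mineral
#'   compartments by the flat coverage-based fraction;
#' * `none`: no change.
#' A ledger can be protected only once; re-application is a usage error
#' (guarded by the `protection` attribute).
#'
#' @param ledger An export ledger tibble (see [run_scenario()]), with
#'   columns `compartment_id`, `land_class`, `year`, `source`, `nutrient`,
#'   `kg_ha`, `kg`, `particulate`, `retained_kg`.
#' @param practice One of `"none"`, `"ponds"`, `"dams"`, `"wetlands"`,
#'   `"riparian"`.
#' @param models Named list of [retention_model()]s, see
#'   [default_protection_models()].
#' @return The ledger with `retained_kg` filled and attribute `protection`
#'   set to the practice.
#' @export
apply_protection <- function(ledger, practice = c("none", "ponds", "dams",
                                                  "wetlands", "riparian"),
                             models = default_protection_models()) {
  practice <- match.arg(practice)
  prior <- attr(ledger, "protection")
  if (!is.null(prior) && prior != "none") {
    stop_usage("ledger already carries the '", prior,
               "' protection; structures are not applied twice")
  }
  if (practice == "none") {
    attr(ledger, "protection") <- "none"
    return(ledger)
  }
  lg <- ledger
  if (practice %in% c("ponds", "dams")) {
    fun <- if (practice == "ponds") pond_retention else dam_retention
    mod <- models[[if (practice == "ponds") "pond" else "dam"]]
    idx <- lg$land_class == "drained_peat" & lg$source == "dnm" & lg$particulate
    if (any(idx)) {
      sub <- lg[idx, ]
      load <- stats::ave(sub$kg_ha, sub$compartment_id, sub$year, sub$nutrient,
                         FUN = sum)
      lg$retained_kg[idx] <- fun(load, mod) * sub$kg
    }
  } else if (practice == "wetlands") {
    mod <- models$wetland
    idx <- lg$land_class == "drained_peat"
    if (any(idx)) {
      sub <- lg[idx, ]
      load <- stats::ave(sub$kg_ha, sub$compartment_id, sub$year, sub$nutrient,
                         FUN = sum)
      frac <- ifelse(sub$nutrient == "N",
                     wetland_fraction(load, "N", mod),
                     wetland_fraction(load, "P", mod))
      lg$retained_kg[idx] <- frac * sub$kg
    }
  } else if (practice == "riparian") {
    mod <- models$riparian
    frac <- riparian_retention(mod$base_coverage_pct, mod)
    idx <- lg$land_class == "mineral"
    lg$retained_kg[idx] <- frac * lg$kg[idx]
  }
  stopifnot(all(lg$retained_kg <= lg$kg + 1e-12))
  attr(lg, "protection") <- practice
  lg
}
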