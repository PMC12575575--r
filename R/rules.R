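#' Management rule set
#'
#' All numeric thresholds of the silvicultural rule engine in one overridable
#' object. The final-felling diameters and thinning basal-area levels are
#' editable configuration defaults in the spirit of the Finnish silvicultural
#' recommendations (they are not empirical constants of the export models);
#' the windows for fertilization and ditch-network maintenance (DNM), the
#' extended-rotation diameter multiplier and the growth multipliers are fixed
#' study conditions.
#'
#' @param final_felling_min_d Data frame with columns `species`, `fertility`,
#'   `min_d_cm`: the minimum mean diameter that must be *exceeded* for a
#'   final felling under rotation forestry.
#' @param erp_diameter_multiplier Multiplier (default 1.10) applied to the
#'   final-felling diameter under the extended-rotation system.
#' @param thinning_limit_ba Basal area (m2/ha) above which a commercial
#'   thinning is triggered.
#' @param post_thinning_ba Basal area (m2/ha) remaining after a thinning.
#' @param ccf_threshold_a,ccf_threshold_b Intercept and slope of the
#'   continuous-cover harvest threshold `BA_thr = a + b * mean_d`, evaluated
#'   at the reference discount rate and temperature sum.
#' @param ccf_discount_rate Discount rate used by the continuous-cover
#'   guideline (default 0.03).
#' @param ccf_discount_exponent Elasticity of the threshold with respect to
#'   the discount rate: the threshold is scaled by
#'   `(rate / 0.03)^ccf_discount_exponent` (negative: impatient owners cut at
#'   lower basal areas).
#' @param ccf_ts_ref Reference temperature sum for the threshold; the
#'   threshold scales with `sqrt(ts / ccf_ts_ref)`.
#' @param ccf_residual_ba Basal area (m2/ha) left after a continuous-cover
#'   harvest.
#' @param ccf_intensity_power Exponent shaping how removal intensity grows
#'   toward larger diameter cohorts.
#' @param ccf_max_intensity Cap on the per-cohort removal fraction.
#' @param fert_mineral Mineral-soil nitrogen fertilization window: diameter
#'   (cm) and basal-area (m2/ha) ranges, minimum years since the previous
#'   fertilization (strict), and the eligible site-species pairs.
#' @param fert_peat Drained-peat (wood-ash) fertilization window, same
#'   structure; interval default > 50 years so a stand is fertilized at most
#'   once in a 50-year horizon.
#' @param dnm DNM window: diameter and basal-area ranges, minimum elapsed
#'   years since the previous DNM (inclusive), and the maximum growing-stock
#'   volume (m3/ha) above which maintenance is skipped because stand
#'   evapotranspiration keeps the water table low on its own.
#' @param regeneration Named list per fertility class giving species
#'   probabilities and the regeneration method.
#' @param regen_stems Stems/ha established by planting, seeding and natural
#'   (seed-tree) regeneration.
#' @param regen_d_cm Initial cohort diameter of regeneration (cm).
#'
#' @return A list of class `management_rules`.
#' @export
management_rules <- function(
    final_felling_min_d = default_felling_diameters(),
    erp_diameter_multiplier = 1.10,
    thinning_limit_ba = 24,
    post_thinning_ba = 16,
    ccf_threshold_a = 12,
    ccf_threshold_b = 0.5,
    ccf_discount_rate = 0.03,
    ccf_discount_exponent = -0.3,
    ccf_ts_ref = 1050,
    ccf_residual_ba = 12,
    ccf_intensity_power = 1.5,
    ccf_max_intensity = 0.9,
    fert_mineral = list(d = c(23, 33), ba = c(15, 40), min_interval = 10,
                        eligible = list(c("xeric", "pine"), c("mesic", "spruce"))),
    fert_peat = list(d = c(5, 30), ba = c(10, 40), min_interval = 50),
    dnm = list(d = c(5, 30), ba = c(10, 40), min_elapsed = 30, max_volume = 150),
    regeneration = list(
      herb_rich = list(method = "planting", probs = c(pine = 0, spruce = 0.9, birch = 0.1)),
      mesic = list(method = "planting", probs = c(pine = 0.3, spruce = 0.6, birch = 0.1)),
      sub_xeric = list(method = "seeding", probs = c(pine = 1)),
      xeric = list(method = "seed_tree", probs = c(pine = 1))
    ),
    regen_stems = c(planting = 1800, seeding = 3000, seed_tree = 2000),
    regen_d_cm = 1.0) {
  for (fr in regeneration) {
    if (abs(sum(fr$probs) - 1) > 1e-9) {
      stop_config("regeneration probabilities must sum to 1 per fertility class")
    }
  }
  for (w in list(fert_mineral$d, fert_mineral$ba, fert_peat$d, fert_peat$ba,
                 dnm$d, dnm$ba)) {
    if (w[1] >= w[2]) stop_config("rule windows must have lower bound < upper bound")
  }
  structure(
    list(
      final_felling_min_d = final_felling_min_d,
      erp_diameter_multiplier = erp_diameter_multiplier,
      thinning_limit_ba = thinning_limit_ba,
      post_thinning_ba = post_thinning_ba,
      ccf_threshold_a = ccf_threshold_a, ccf_threshold_b = ccf_threshold_b,
      ccf_discount_rate = ccf_discount_rate,
      ccf_discount_exponent = ccf_discount_exponent,
      ccf_ts_ref = ccf_ts_ref, ccf_residual_ba = ccf_residual_ba,
      ccf_intensity_power = ccf_intensity_power,
      ccf_max_intensity = ccf_max_intensity,
      fert_mineral = fert_mineral, fert_peat = fert_peat, dnm = dnm,
      regeneration = regeneration, regen_stems = regen_stems,
      regen_d_cm = regen_d_cm
    ),
    class = "management_rules"
  )
}

#' Default final-felling diameter table
#'
#' Editable configuration in the 24-28 cm range by fertility, not empirical
#' model constants.
#' @return Data frame with columns `species`, `fertility`, `min_d_cm`.
#' @export
default_felling_diameters <- function() {
  grid <- expand.grid(
    species = SPECIES_LEVELS, fertility = FERTILITY_LEVELS,
    stringsAsFactors = FALSE
  )
  base <- c(herb_rich = 27, mesic = 26, sub_xeric = 25, xeric = 24)
  grid$min_d_cm <- base[grid$fertility] + ifelse(grid$species == "spruce", 1, 0)
  grid
}

felling_min_d <- function(rules, species, fertility) {
  tab <- rules$final_felling_min_d
  hit <- tab$min_d_cm[tab$species == species & tab$fertility == fertility]
  if (!length(hit)) stop_config("no felling diameter for ", species, "/", fertility)
  hit[1L]
}

#' Read a management rule set from a YAML file
#'
#' Scalar fields override the defaults of [management_rules()]; the
#' final-felling table may be given as a list of `{species, fertility,
#' min_d_cm}` records.
#' @param path Path to a YAML file.
#' @return A `management_rules` object.
#' @export
rules_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$final_felling_min_d)) {
    raw$final_felling_min_d <- do.call(
      rbind, lapply(raw$final_felling_min_d, as.data.frame)
    )
  }
  defaults <- management_rules()
  merged <- merge_config(unclass(defaults), raw)
  do.call(management_rules, merged)
}
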