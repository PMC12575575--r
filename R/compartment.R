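#' Construct a single forest compartment
#'
#' A compartment is the atomic simulation unit: one forest stand with a known
#' area, land class, site fertility, and a diameter-class table describing its
#' structure. Mean diameter, basal area and volume are always derived from the
#' diameter-class table, so the three summaries and the table cannot drift
#' apart.
#'
#' @param id Compartment identifier (character).
#' @param area_ha Compartment area in hectares (> 0).
#' @param land_class One of `"mineral"`, `"drained_peat"`, `"undrained_peat"`,
#'   `"nonforest"`.
#' @param fertility Site fertility class, one of `"herb_rich"`, `"mesic"`,
#'   `"sub_xeric"`, `"xeric"` (ordered from most to least productive).
#' @param dominant_species One of `"pine"`, `"spruce"`, `"birch"`, `"mixed"`.
#' @param origin Regeneration origin: `"planted"`, `"seeded"` or `"natural"`.
#'   Planted stands grow 10% and seeded stands 5% faster in diameter than
#'   natural stands.
#' @param diameter_classes Data frame with columns `mid_cm` (class midpoint,
#'   cm) and `stems_ha` (stems per hectare, may be fractional). May have zero
#'   rows for an unstocked compartment.
#' @param age_years Stand age in years.
#' @param ditch_depth_cm Average ditch depth (cm); required for (and only
#'   allowed on) drained peatland compartments. Default 60 cm, the typical
#'   depth where more than a decade has passed since ditch-network
#'   maintenance.
#' @param years_since_dnm Years since the last ditch-network maintenance
#'   (drained peat only).
#' @param years_since_fertilization Years since the last fertilization.
#' @param growth Growth parameterization used for the volume function; see
#'   [growth_params()].
#'
#' @return An object of class `stand_compartment`: a list with the fields
#'   above plus derived `mean_diameter_cm`, `basal_area_m2_ha` and
#'   `volume_m3_ha`.
#' @export
#' @examples
#' cmp <- compartment(
#'   id = "c1", area_ha = 3, land_class = "drained_peat", fertility = "mesic",
#'   dominant_species = "pine", origin = "natural",
#'   diameter_classes = data.frame(mid_cm = c(11, 15, 19), stems_ha = c(500, 400, 250)),
#'   age_years = 55
#' )
#' cmp$volume_m3_ha
compartment <- function(id, area_ha, land_class, fertility, dominant_species,
                        origin, diameter_classes, age_years,
                        ditch_depth_cm = if (land_class == "drained_peat") 60 else NA_real_,
                        years_since_dnm = if (land_class == "drained_peat") 30 else NA_real_,
                        years_since_fertilization = 100,
                        growth = growth_params()) {
  assert_scalar_num(area_ha, "area_ha", 0, strict = TRUE)
  match_token(land_class, LAND_CLASSES, "land_class")
  match_token(fertility, FERTILITY_LEVELS, "fertility")
  match_token(dominant_species, SPECIES_LEVELS, "dominant_species")
  match_token(origin, ORIGIN_LEVELS, "origin")
  if (!is.data.frame(diameter_classes) ||
      !all(c("mid_cm", "stems_ha") %in% names(diameter_classes))) {
    stop_config("diameter_classes must be a data frame with mid_cm and stems_ha")
  }
  if (any(diameter_classes$stems_ha < 0) || any(diameter_classes$mid_cm <= 0)) {
    stop_config("diameter_classes must have positive midpoints and nonnegative stems")
  }
  if (land_class == "drained_peat") {
    assert_scalar_num(ditch_depth_cm, "ditch_depth_cm", 0, strict = TRUE)
  } else if (!is.na(ditch_depth_cm)) {
    stop_config("ditch_depth_cm is only meaningful for drained_peat compartments")
  }
  s <- stand_summaries(diameter_classes$mid_cm, diameter_classes$stems_ha, growth)
  structure(
    list(
      id = as.character(id), area_ha = area_ha, land_class = land_class,
      fertility = fertility, dominant_species = dominant_species,
      origin = origin,
      diameter_classes = as.data.frame(diameter_classes)[c("mid_cm", "stems_ha")],
      mean_diameter_cm = s$mean_d, basal_area_m2_ha = s$ba,
      volume_m3_ha = s$volume, age_years = age_years,
      ditch_depth_cm = ditch_depth_cm, years_since_dnm = years_since_dnm,
      years_since_fertilization = years_since_fertilization,
      dnm_pending = FALSE, fert_this_rotation = FALSE, boost_years_left = 0
    ),
    class = "stand_compartment"
  )
}

#' Stand summaries from a diameter-class table
#'
#' Basal area is the exact sum of class cross-sections,
#' `sum(stems * pi * (mid/200)^2)`; volume uses the two-parameter class volume
#' function `v(d) = vol_a * d^vol_b` (m3 per stem); mean diameter is the
#' basal-area-weighted mean class midpoint, the convention used by Finnish
#' silvicultural recommendations for maturity checks.
#'
#' @param mid_cm Numeric vector of class midpoints (cm).
#' @param stems_ha Numeric vector of stems per hectare.
#' @param growth Growth parameterization, see [growth_params()].
#' @return List with `ba` (m2/ha), `volume` (m3/ha) and `mean_d` (cm).
#' @export
stand_summaries <- function(mid_cm, stems_ha, growth = growth_params()) {
  if (any(stems_ha < 0)) stop_usage("negative stems per hectare")
  ba_i <- stems_ha * pi * (mid_cm / 200)^2
  ba <- sum(ba_i)
  list(
    ba = ba,
    volume = sum(stems_ha * growth$vol_a * mid_cm^growth$vol_b),
    mean_d = if (ba > 0) sum(ba_i * mid_cm) / ba else 0
  )
}

#' @export
print.stand_compartment <- function(x, ...) {
  cat(sprintf(
    "<stand_compartment %s> %s/%s %s, %.1f ha\n  d=%.1f cm, BA=%.1f m2/ha, V=%.1f m3/ha, age %s\n",
    x$id, x$land_class, x$fertility, x$dominant_species, x$area_ha,
    x$mean_diameter_cm, x$basal_area_m2_ha, x$volume_m3_ha, x$age_years
  ))
  invisible(x)
}

# Refresh the derived summaries after the diameter-class table changed.
refresh_summaries <- function(cmp, growth) {
  s <- stand_summaries(cmp$diameter_classes$mid_cm, cmp$diameter_classes$stems_ha, growth)
  cmp$mean_diameter_cm <- s$mean_d
  cmp$basal_area_m2_ha <- s$ba
  cmp$volume_m3_ha <- s$volume
  cmp
}

#' Extract one compartment from a stand register
#'
#' @param register A `stand_register`, see [generate_catchment()].
#' @param id Compartment identifier.
#' @param growth Growth parameterization for the derived summaries.
#' @return A [compartment()] object, with the compartment's event history
#'   attached as attribute `"events"`.
#' @export
as_compartment <- function(register, id, growth = growth_params()) {
  i <- match(id, register$compartments$id)
  if (is.na(i)) stop_usage("no compartment with id '", id, "'")
  row <- register$compartments[i, ]
  cmp <- compartment(
    id = row$id, area_ha = row$area_ha, land_class = row$land_class,
    fertility = row$fertility, dominant_species = row$dominant_species,
    origin = row$origin, diameter_classes = row$diameter_classes[[1L]],
    age_years = row$age_years, ditch_depth_cm = row$ditch_depth_cm,
    years_since_dnm = row$years_since_dnm,
    years_since_fertilization = row$years_since_fertilization,
    growth = growth
  )
  attr(cmp, "events") <- register$events[register$events$compartment_id == id, ]
  cmp
}
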