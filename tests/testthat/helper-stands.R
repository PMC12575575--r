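# Small fixture builders shared across test files.

make_stand <- function(land_class = "mineral", fertility = "mesic",
                       species = "spruce", origin = "natural",
                       mids = c(11, 15, 19), stems = c(500, 400, 250),
                       age = 50, id = "t1", area = 2, ...) {
  compartment(
    id = id, area_ha = area, land_class = land_class, fertility = fertility,
    dominant_species = species, origin = origin,
    diameter_classes = data.frame(mid_cm = mids, stems_ha = stems),
    age_years = age, ...
  )
}

# single-cohort stand with a prescribed mean diameter and basal area
mono_stand <- function(d_cm, ba_m2, ...) {
  stems <- ba_m2 / (pi * (d_cm / 200)^2)
  make_stand(mids = d_cm, stems = stems, ...)
}

# one-compartment register around a compartment object
tiny_register <- function(cmps, events = NULL) {
  rows <- lapply(cmps, function(cmp) {
    tibble::tibble(
      id = cmp$id, area_ha = cmp$area_ha, land_class = cmp$land_class,
      fertility = cmp$fertility, dominant_species = cmp$dominant_species,
      origin = cmp$origin, diameter_classes = list(cmp$diameter_classes),
      mean_diameter_cm = cmp$mean_diameter_cm,
      basal_area_m2_ha = cmp$basal_area_m2_ha,
      volume_m3_ha = cmp$volume_m3_ha, age_years = cmp$age_years,
      ditch_depth_cm = cmp$ditch_depth_cm,
      years_since_dnm = cmp$years_since_dnm,
      years_since_fertilization = cmp$years_since_fertilization
    )
  })
  ev <- events %||% tibble::tibble(
    compartment_id = character(), event_type = character(), year = integer(),
    removed_volume_m3_ha = numeric(), treated_area_ha = numeric()
  )
  structure(
    list(compartments = dplyr::bind_rows(rows), events = ev, config = NULL),
    class = "stand_register"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
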