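#' Configuration of a synthetic catchment
#'
#' The generator emulates a large boreal river catchment in central Finland:
#' 3824 km2 with 40% mineral-soil forests, 31.5% forestry-drained peatlands,
#' 21.1% undrained open and forested peatlands and the remainder non-forest.
#' The fertility breakdowns and initial stand-state distributions are
#' plausible boreal defaults only -- the source landscape's fertility
#' composition is not documented -- and should be overridden where better
#' information exists.
#'
#' @param total_area_km2 Total catchment area (default 3824).
#' @param n_compartments Number of compartments to generate (default 2000).
#'   Areas are drawn from a log-normal (median `area_median_ha`) for shape,
#'   then rescaled within each land class so that class areas match the
#'   configured shares exactly and the total matches `total_area_km2`.
#' @param land_class_shares Named shares summing to 1.
#' @param fertility_shares Named list per land class of fertility-class
#'   probabilities (placeholder defaults; flagged, not data).
#' @param species_probs Named list per fertility class of dominant-species
#'   probabilities.
#' @param origin_probs Named list per land class of regeneration-origin
#'   probabilities.
#' @param area_median_ha Log-normal median of the compartment-area draw.
#' @param area_sdlog Log-normal sdlog.
#' @param d_range Named list per fertility class: range (cm) of the initial
#'   basal-area-weighted mean diameter draw.
#' @param ba_range Range (m2/ha) of the initial basal-area draw.
#' @param precut_fraction Fraction of mineral compartments carrying a
#'   pre-simulation clear-cut (default 0.10) so that residual exports of
#'   past fellings appear in the first period.
#' @param precut_years Candidate years for those clear-cuts (negative,
#'   default -1 ... -9).
#' @param ditch_depth_cm Average ditch depth assigned to drained peatlands
#'   (default 60 cm).
#' @param seed Random seed.
#' @return A list of class `catchment_config`.
#' @export
catchment_config <- function(
    total_area_km2 = 3824,
    n_compartments = 2000,
    land_class_shares = c(mineral = 0.40, drained_peat = 0.315,
                          undrained_peat = 0.211, nonforest = 0.074),
    fertility_shares = list(
      mineral = c(herb_rich = 0.10, mesic = 0.45, sub_xeric = 0.35, xeric = 0.10),
      drained_peat = c(herb_rich = 0.10, mesic = 0.35, sub_xeric = 0.40, xeric = 0.15),
      undrained_peat = c(herb_rich = 0.05, mesic = 0.25, sub_xeric = 0.45, xeric = 0.25),
      nonforest = c(herb_rich = 0.25, mesic = 0.25, sub_xeric = 0.25, xeric = 0.25)
    ),
    species_probs = list(
      herb_rich = c(pine = 0.05, spruce = 0.65, birch = 0.20, mixed = 0.10),
      mesic = c(pine = 0.35, spruce = 0.45, birch = 0.10, mixed = 0.10),
      sub_xeric = c(pine = 0.70, spruce = 0.10, birch = 0.05, mixed = 0.15),
      xeric = c(pine = 0.90, spruce = 0.00, birch = 0.00, mixed = 0.10)
    ),
    origin_probs = list(
      mineral = c(planted = 0.40, seeded = 0.20, natural = 0.40),
      drained_peat = c(planted = 0.10, seeded = 0.10, natural = 0.80),
      undrained_peat = c(planted = 0, seeded = 0, natural = 1),
      nonforest = c(planted = 0, seeded = 0, natural = 1)
    ),
    area_median_ha = 3,
    area_sdlog = 0.6,
    d_range = list(herb_rich = c(8, 28), mesic = c(7, 28),
                   sub_xeric = c(6, 26), xeric = c(5, 24)),
    ba_range = c(8, 28),
    precut_fraction = 0.10,
    precut_years = -(1:9),
    ditch_depth_cm = 60,
    seed = 1L) {
  if (abs(sum(land_class_shares) - 1) > 1e-9) {
    stop_config("land-class shares must sum to 1")
  }
  if (any(land_class_shares < 0)) stop_config("land-class shares must be nonnegative")
  assert_scalar_num(total_area_km2, "total_area_km2", 0, strict = TRUE)
  assert_scalar_num(n_compartments, "n_compartments", 0, strict = TRUE)
  assert_scalar_num(area_median_ha, "area_median_ha", 0, strict = TRUE)
  for (r in c(d_range, list(ba_range))) {
    if (any(r <= 0) || r[1] >= r[2]) stop_config("distribution bounds must be positive and increasing")
  }
  if (precut_fraction < 0 || precut_fraction > 1) {
    stop_config("precut_fraction must be in [0, 1]")
  }
  structure(
    list(
      total_area_km2 = total_area_km2, n_compartments = as.integer(n_compartments),
      land_class_shares = land_class_shares, fertility_shares = fertility_shares,
      species_probs = species_probs, origin_probs = origin_probs,
      area_median_ha = area_median_ha, area_sdlog = area_sdlog,
      d_range = d_range, ba_range = ba_range,
      precut_fraction = precut_fraction, precut_years = precut_years,
      ditch_depth_cm = ditch_depth_cm, seed = as.integer(seed)
    ),
    class = "catchment_config"
  )
}

#' Read a catchment configuration from YAML
#' @param path YAML file whose fields override [catchment_config()] defaults.
#' @return A `catchment_config`.
#' @export
catchment_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  listy <- c("land_class_shares")
  for (nm in intersect(names(raw), listy)) raw[[nm]] <- unlist(raw[[nm]])
  for (nm in intersect(names(raw), c("fertility_shares", "species_probs", "origin_probs"))) {
    raw[[nm]] <- lapply(raw[[nm]], unlist)
  }
  for (nm in intersect(names(raw), c("d_range", "ba_range", "precut_years"))) {
    raw[[nm]] <- if (nm == "d_range") lapply(raw[[nm]], unlist) else unlist(raw[[nm]])
  }
  do.call(catchment_config, merge_config(unclass(catchment_config()), raw))
}

sample_token <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# Truncated-Weibull diameter distribution binned into 2-cm classes, scaled
# to a target basal area.
weibull_classes <- function(mean_d, ba_target, shape = 3) {
  scale <- mean_d / gamma(1 + 1 / shape)
  upper <- qweibull(0.995, shape, scale)
  mids <- seq(1, max(3, ceiling(upper)), by = 2)
  w <- dweibull(mids, shape, scale)
  w <- w / sum(w)
  ba_unit <- sum(w * pi * (mids / 200)^2)
  stems <- w * (ba_target / ba_unit)
  keep <- stems > 1e-6
  data.frame(mid_cm = mids[keep], stems_ha = stems[keep])
}

#' Generate a seeded synthetic stand register
#'
#' Draws compartments whose land-class composition matches the configured
#' shares exactly (areas are rescaled within class), assigns fertility,
#' species, origin and an initial diameter-class structure, gives every
#' drained-peat compartment the configured ditch depth, and plants a
#' pre-simulation clear-cut history on a fraction of mineral compartments
#' (those stands are re-initialized as young regeneration of the cut's age).
#' The same seed always yields an identical register.
#'
#' @param config A [catchment_config()].
#' @param growth Growth parameterization used for the volume function.
#' @return A list of class `stand_register` with elements `compartments`
#'   (tibble, one row per compartment, diameter classes as a list column)
#'   and `events` (tibble of dated management events; pre-simulation history
#'   has negative years).
#' @export
#' @examples
#' reg <- generate_catchment(catchment_config(n_compartments = 50, seed = 7))
#' table(reg$compartments$land_class)
generate_catchment <- function(config = catchment_config(),
                               growth = growth_params()) {
  set.seed(config$seed)
  n <- config$n_compartments
  total_ha <- config$total_area_km2 * 100

  # exact class counts by largest remainder, exact class areas by rescaling
  shares <- config$land_class_shares
  raw_counts <- shares * n
  counts <- floor(raw_counts)
  rem <- n - sum(counts)
  if (rem > 0) {
    top_up <- order(raw_counts - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top_up] <- counts[top_up] + 1
  }
  land_class <- sample(rep(names(shares), counts))

  areas <- rlnorm(n, log(config$area_median_ha), config$area_sdlog)
  for (lc in names(shares)) {
    i <- land_class == lc
    if (any(i)) areas[i] <- areas[i] * (shares[[lc]] * total_ha / sum(areas[i]))
  }

  fertility <- character(n)
  for (lc in names(shares)) {
    i <- land_class == lc
    if (any(i)) fertility[i] <- sample_token(sum(i), config$fertility_shares[[lc]])
  }
  species <- character(n)
  for (fc in FERTILITY_LEVELS) {
    i <- fertility == fc
    if (any(i)) species[i] <- sample_token(sum(i), config$species_probs[[fc]])
  }
  origin <- character(n)
  for (lc in names(shares)) {
    i <- land_class == lc
    if (any(i)) origin[i] <- sample_token(sum(i), config$origin_probs[[lc]])
  }

  forested <- land_class %in% c("mineral", "drained_peat")
  classes <- vector("list", n)
  age <- numeric(n)
  for (i in seq_len(n)) {
    if (forested[i]) {
      d_mean <- runif(1, config$d_range[[fertility[i]]][1],
                      config$d_range[[fertility[i]]][2])
      ba <- runif(1, config$ba_range[1], config$ba_range[2])
      classes[[i]] <- weibull_classes(d_mean, ba)
      age[i] <- round(d_mean / 0.3 + runif(1, -5, 5))
    } else {
      classes[[i]] <- data.frame(mid_cm = numeric(), stems_ha = numeric())
      age[i] <- 0
    }
  }

  drained <- land_class == "drained_peat"
  ditch <- ifelse(drained, config$ditch_depth_cm, NA_real_)
  ysd <- ifelse(drained, round(runif(n, 10, 40)), NA_real_)
  ysf <- round(runif(n, 20, 80))

  ids <- sprintf("c%05d", seq_len(n))

  # pre-simulation clear-cut history on a fraction of mineral compartments
  events <- list()
  mineral_idx <- which(land_class == "mineral")
  n_cut <- round(config$precut_fraction * length(mineral_idx))
  if (n_cut > 0) {
    cut_idx <- sample(mineral_idx, n_cut)
    cut_year <- sample(config$precut_years, n_cut, replace = TRUE)
    for (k in seq_along(cut_idx)) {
      i <- cut_idx[k]
      yrs_ago <- -cut_year[k]
      events[[length(events) + 1L]] <- tibble::tibble(
        compartment_id = ids[i], event_type = "clear_cut",
        year = as.integer(cut_year[k]),
        removed_volume_m3_ha = runif(1, 150, 250), treated_area_ha = areas[i]
      )
      rg_probs <- config$species_probs[[fertility[i]]]
      classes[[i]] <- data.frame(
        mid_cm = max(0.8, 0.45 * yrs_ago),
        stems_ha = 2000
      )
      species[i] <- sample_token(1, rg_probs)
      origin[i] <- if (fertility[i] %in% c("herb_rich", "mesic")) "planted" else "seeded"
      age[i] <- yrs_ago
    }
  }

  summ <- lapply(classes, function(cl) stand_summaries(cl$mid_cm, cl$stems_ha, growth))
  compartments <- tibble::tibble(
    id = ids, area_ha = areas, land_class = land_class, fertility = fertility,
    dominant_species = species, origin = origin,
    diameter_classes = classes,
    mean_diameter_cm = vapply(summ, `[[`, numeric(1), "mean_d"),
    basal_area_m2_ha = vapply(summ, `[[`, numeric(1), "ba"),
    volume_m3_ha = vapply(summ, `[[`, numeric(1), "volume"),
    age_years = age, ditch_depth_cm = ditch, years_since_dnm = ysd,
    years_since_fertilization = ysf
  )
  events <- if (length(events)) dplyr::bind_rows(events) else tibble::tibble(
    compartment_id = character(), event_type = character(), year = integer(),
    removed_volume_m3_ha = numeric(), treated_area_ha = numeric()
  )
  structure(
    list(compartments = compartments, events = events, config = config),
    class = "stand_register"
  )
}

#' @export
print.stand_register <- function(x, ...) {
  areas <- tapply(x$compartments$area_ha, x$compartments$land_class, sum)
  cat(sprintf(
    "<stand_register> %d compartments, %.0f km2\n",
    nrow(x$compartments), sum(x$compartments$area_ha) / 100
  ))
  for (lc in names(areas)) {
    cat(sprintf("  %-15s %6.1f km2 (%.1f%%)\n", lc, areas[[lc]] / 100,
                100 * areas[[lc]] / sum(areas)))
  }
  cat(sprintf("  %d events on record\n", nrow(x$events)))
  invisible(x)
}

#' Subset a register by land class
#' @param register A `stand_register`.
#' @param land_classes Character vector of land classes to keep.
#' @return A `stand_register` with matching compartments and their events.
#' @export
subset_register <- function(register, land_classes) {
  keep <- register$compartments$land_class %in% land_classes
  ids <- register$compartments$id[keep]
  structure(
    list(
      compartments = register$compartments[keep, ],
      events = register$events[register$events$compartment_id %in% ids, ],
      config = register$config
    ),
    class = "stand_register"
  )
}

#' Validate register invariants
#'
#' Checks field domains, positivity, the presence of ditch depth exactly on
#' drained-peat rows, and that the stored mean diameter, basal area and
#' volume agree with the diameter-class tables under the stand-structure
#' conversion within `tol` (relative).
#'
#' @param register A `stand_register`.
#' @param growth Growth parameterization for the volume function.
#' @param tol Relative tolerance for the summary consistency check.
#' @return Invisibly `TRUE`; errors describe the offending row.
#' @export
validate_register <- function(register, growth = growth_params(), tol = 1e-6) {
  cmp <- register$compartments
  match_token(cmp$land_class, LAND_CLASSES, "land_class", row = seq_len(nrow(cmp)))
  match_token(cmp$fertility, FERTILITY_LEVELS, "fertility", row = seq_len(nrow(cmp)))
  match_token(cmp$dominant_species, SPECIES_LEVELS, "dominant_species",
              row = seq_len(nrow(cmp)))
  match_token(cmp$origin, ORIGIN_LEVELS, "origin", row = seq_len(nrow(cmp)))
  if (any(cmp$area_ha <= 0)) stop_schema("area_ha must be > 0")
  drained <- cmp$land_class == "drained_peat"
  if (any(drained & (is.na(cmp$ditch_depth_cm) | cmp$ditch_depth_cm <= 0))) {
    stop_schema("missing ditch depth on drained_peat row ",
                which(drained & is.na(cmp$ditch_depth_cm))[1L])
  }
  if (any(!drained & !is.na(cmp$ditch_depth_cm))) {
    stop_schema("ditch depth present on non-drained row ",
                which(!drained & !is.na(cmp$ditch_depth_cm))[1L])
  }
  for (i in seq_len(nrow(cmp))) {
    cl <- cmp$diameter_classes[[i]]
    s <- stand_summaries(cl$mid_cm, cl$stems_ha, growth)
    if (abs(s$ba - cmp$basal_area_m2_ha[i]) > tol * max(1, s$ba) ||
        abs(s$volume - cmp$volume_m3_ha[i]) > tol * max(1, s$volume) ||
        abs(s$mean_d - cmp$mean_diameter_cm[i]) > tol * max(1, s$mean_d)) {
      stop_schema("summaries inconsistent with diameter classes on row ", i)
    }
  }
  if (nrow(register$events)) {
    match_token(register$events$event_type, EVENT_TYPES, "event_type",
                row = seq_len(nrow(register$events)))
    nonharv <- !register$events$event_type %in% HARVEST_EVENTS
    if (any(nonharv & register$events$removed_volume_m3_ha != 0)) {
      stop_schema("non-harvest events must have zero removed volume")
    }
  }
  invisible(TRUE)
}

pack_classes <- function(cl) {
  if (!nrow(cl)) return("")
  paste(sprintf("%.12g:%.12g", cl$mid_cm, cl$stems_ha), collapse = ";")
}

unpack_classes <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(mid_cm = numeric(), stems_ha = numeric()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(
    mid_cm = as.numeric(vapply(parts, `[[`, character(1), 1L)),
    stems_ha = as.numeric(vapply(parts, `[[`, character(1), 2L))
  )
}

#' Write a stand register to CSV
#'
#' Writes `register.csv` (one compartment per row; the diameter-class table
#' packed as `mid:stems` pairs separated by `;`) and `events.csv` (event
#' history keyed by compartment id) into a directory, UTF-8, documented
#' column order. [read_register()] of the result reproduces the register
#' field for field.
#'
#' @param register A `stand_register`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_register <- function(register, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cmp <- register$compartments
  flat <- data.frame(
    id = cmp$id, area_ha = sprintf("%.12g", cmp$area_ha),
    land_class = cmp$land_class, fertility = cmp$fertility,
    dominant_species = cmp$dominant_species, origin = cmp$origin,
    mean_diameter_cm = sprintf("%.12g", cmp$mean_diameter_cm),
    basal_area_m2_ha = sprintf("%.12g", cmp$basal_area_m2_ha),
    volume_m3_ha = sprintf("%.12g", cmp$volume_m3_ha),
    age_years = cmp$age_years,
    ditch_depth_cm = ifelse(is.na(cmp$ditch_depth_cm), "",
                            sprintf("%.12g", cmp$ditch_depth_cm)),
    years_since_dnm = ifelse(is.na(cmp$years_since_dnm), "",
                             sprintf("%.12g", cmp$years_since_dnm)),
    years_since_fertilization = cmp$years_since_fertilization,
    diameter_classes = vapply(cmp$diameter_classes, pack_classes, character(1))
  )
  reg_path <- file.path(dir, "register.csv")
  ev_path <- file.path(dir, "events.csv")
  write.csv(flat, reg_path, row.names = FALSE, fileEncoding = "UTF-8")
  ev <- register$events
  ev$removed_volume_m3_ha <- sprintf("%.12g", ev$removed_volume_m3_ha)
  ev$treated_area_ha <- sprintf("%.12g", ev$treated_area_ha)
  write.csv(ev, ev_path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(reg_path, ev_path))
}

#' Read a stand register from CSV
#'
#' Reads the `register.csv` / `events.csv` pair written by
#' [write_register()]. Unknown land-class or fertility tokens and missing
#' ditch depths on drained peat are schema errors reporting the row number;
#' a file with only a header yields an empty register.
#'
#' @param dir Directory containing `register.csv` and `events.csv` (the
#'   events file may be absent).
#' @param growth Growth parameterization for the consistency check.
#' @param validate Run [validate_register()] on the result (default TRUE).
#' @return A `stand_register`.
#' @export
read_register <- function(dir, growth = growth_params(), validate = TRUE) {
  reg_path <- file.path(dir, "register.csv")
  if (!file.exists(reg_path)) stop_schema("no register.csv in ", dir)
  flat <- read.csv(reg_path, stringsAsFactors = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  required <- c("id", "area_ha", "land_class", "fertility", "dominant_species",
                "origin", "age_years", "diameter_classes")
  missing <- setdiff(required, names(flat))
  if (length(missing)) stop_schema("register.csv lacks columns: ",
                                   paste(missing, collapse = ", "))
  n <- nrow(flat)
  num <- function(x) suppressWarnings(as.numeric(x))
  blank_na <- function(x) ifelse(is.na(x) | x == "", NA_real_, num(x))
  classes <- lapply(flat$diameter_classes, unpack_classes)
  summ <- lapply(classes, function(cl) stand_summaries(cl$mid_cm, cl$stems_ha, growth))
  compartments <- tibble::tibble(
    id = flat$id, area_ha = num(flat$area_ha), land_class = flat$land_class,
    fertility = flat$fertility, dominant_species = flat$dominant_species,
    origin = flat$origin, diameter_classes = classes,
    mean_diameter_cm = vapply(summ, `[[`, numeric(1), "mean_d"),
    basal_area_m2_ha = vapply(summ, `[[`, numeric(1), "ba"),
    volume_m3_ha = vapply(summ, `[[`, numeric(1), "volume"),
    age_years = num(flat$age_years),
    ditch_depth_cm = blank_na(flat$ditch_depth_cm %||% rep("", n)),
    years_since_dnm = blank_na(flat$years_since_dnm %||% rep("", n)),
    years_since_fertilization = num(flat$years_since_fertilization %||% rep("100", n))
  )
  ev_path <- file.path(dir, "events.csv")
  events <- if (file.exists(ev_path)) {
    ev <- read.csv(ev_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    tibble::tibble(
      compartment_id = as.character(ev$compartment_id),
      event_type = as.character(ev$event_type), year = as.integer(ev$year),
      removed_volume_m3_ha = as.numeric(ev$removed_volume_m3_ha),
      treated_area_ha = as.numeric(ev$treated_area_ha)
    )
  } else {
    tibble::tibble(
      compartment_id = character(), event_type = character(), year = integer(),
      removed_volume_m3_ha = numeric(), treated_area_ha = numeric()
    )
  }
  register <- structure(
    list(compartments = compartments, events = events, config = NULL),
    class = "stand_register"
  )
  if (validate) validate_register(register, growth)
  register
}
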