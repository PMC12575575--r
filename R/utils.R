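`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("borealnp_config_error", "error")))
}

#' @noRd
stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("borealnp_schema_error", "error")))
}

#' @noRd
stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("borealnp_usage_error", "error")))
}

#' @noRd
stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("borealnp_domain_error", "error")))
}

assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config(name, " must be a single finite number")
  }
  if (strict && x <= lower) stop_config(name, " must be > ", lower)
  if (!strict && x < lower) stop_config(name, " must be >= ", lower)
  invisible(x)
}

match_token <- function(x, choices, name, row = NULL) {
  bad <- !(x %in% choices)
  if (any(bad)) {
    where <- if (is.null(row)) "" else paste0(" (row ", row[which(bad)[1L]], ")")
    stop_schema(
      "unknown ", name, " '", x[which(bad)[1L]], "'", where,
      "; expected one of: ", paste(choices, collapse = ", ")
    )
  }
  x
}

# Recursive merge of a user-supplied list into nested defaults; scalar and
# vector leaves replace, lists merge by name.
merge_config <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  if (!is.list(defaults) || !is.list(override)) return(override)
  for (nm in names(override)) {
    defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]])
  }
  defaults
}

LAND_CLASSES <- c("mineral", "drained_peat", "undrained_peat", "nonforest")
FERTILITY_LEVELS <- c("herb_rich", "mesic", "sub_xeric", "xeric")
SPECIES_LEVELS <- c("pine", "spruce", "birch", "mixed")
ORIGIN_LEVELS <- c("planted", "seeded", "natural")
EVENT_TYPES <- c(
  "clear_cut", "seed_tree_felling", "thinning_below", "thinning_above",
  "ccf_harvest", "site_preparation", "planting", "seeding", "tending",
  "fertilization_mineral_N", "fertilization_peat_ash", "dnm"
)
HARVEST_EVENTS <- c(
  "clear_cut", "seed_tree_felling", "thinning_below", "thinning_above",
  "ccf_harvest"
)
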