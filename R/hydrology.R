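#' August water-table level in a drained peatland stand
#'
#' Empirical regression for the late-summer (August) water-table depth in
#' drained peatland forests, fitted to 460 Finnish sample plots:
#'
#' \deqn{WTL = 47.92 + 159.83(1-0.3^{V/90}) - 30.684(1-0.3^{V/90})\ln S
#'       + 8.095 \ln D - 0.73\,LAT - 0.185\,S}
#'
#' Sign convention: positive values are depth below the soil surface in cm,
#' so larger WTL means a deeper (lower) water table. A larger growing stock
#' transpires more and draws the water table down; deeper ditches drain more.
#'
#' @param V Growing-stock volume (m3/ha), >= 0. Vectorized.
#' @param S Mean monthly July-August precipitation (mm), > 0.
#' @param D Average ditch depth (cm), > 0.
#' @param LAT Northern latitude (degrees). The calibration data span roughly
#'   59-71 degrees N; values outside that band trigger a warning.
#' @return Water-table depth (cm, positive downward). Deterministic.
#' @export
#' @examples
#' compute_wtl(V = 100, S = 60, D = 60, LAT = 65)  # about 47.7 cm
compute_wtl <- function(V, S, D, LAT) {
  if (any(V < 0)) stop_domain("V must be >= 0")
  if (any(S <= 0)) stop_domain("S must be > 0 (log term)")
  if (any(D <= 0)) stop_domain("D must be > 0 (log term)")
  if (any(LAT <= 59 | LAT >= 71)) {
    warning("LAT outside the 59-71 degree calibration domain")
  }
  g <- 1 - 0.3^(V / 90)
  47.92 + 159.83 * g - 30.684 * g * log(S) + 8.095 * log(D) -
    0.73 * LAT - 0.185 * S
}

#' Legacy-export response curves for drained peatlands
#'
#' Maps the August water-table depth to the annual nitrogen and phosphorus
#' export caused by aerobic peat mineralization (the legacy effect of
#' drainage). The default is a piecewise-linear hinge per fertility class,
#' `export = slope * max(0, WTL - wtl0)`: no mineralization export while the
#' water table is shallower than the reference depth, then a linear rise.
#' The slopes are calibration placeholders standing in for process-simulator
#' output (monotone, ordered by fertility); replace them via the arguments
#' or [legacy_response_from_yaml()].
#'
#' @param wtl0_cm Reference water-table depth (cm) at which the export is
#'   zero. Default 30.
#' @param slopes_n,slopes_p Named vectors (kg/ha/yr per cm of water-table
#'   depth beyond the reference) per fertility class, decreasing from
#'   herb-rich to xeric.
#' @return A list of class `legacy_response`.
#' @export
legacy_response <- function(wtl0_cm = 30,
                            slopes_n = c(herb_rich = 0.055, mesic = 0.042,
                                         sub_xeric = 0.028, xeric = 0.016),
                            slopes_p = c(herb_rich = 0.0040, mesic = 0.0030,
                                         sub_xeric = 0.0020, xeric = 0.0012)) {
  if (any(slopes_n < 0) || any(slopes_p < 0)) {
    stop_config("legacy response slopes must be nonnegative")
  }
  structure(
    list(wtl0_cm = wtl0_cm, slopes_n = slopes_n, slopes_p = slopes_p),
    class = "legacy_response"
  )
}

#' Read legacy-export response parameters from YAML
#' @param path Path to a YAML file with fields `wtl0_cm`, `slopes_n`,
#'   `slopes_p`.
#' @return A `legacy_response` object.
#' @export
legacy_response_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  resp <- legacy_response()
  if (!is.null(raw$wtl0_cm)) resp$wtl0_cm <- raw$wtl0_cm
  for (fld in c("slopes_n", "slopes_p")) {
    for (nm in names(raw[[fld]])) resp[[fld]][[nm]] <- raw[[fld]][[nm]]
  }
  legacy_response(resp$wtl0_cm, resp$slopes_n, resp$slopes_p)
}

#' Annual legacy N and P export at a given water-table depth
#'
#' @param wtl_cm Water-table depth (cm, positive downward). Vectorized.
#' @param fertility Fertility class (scalar or vector recycled against
#'   `wtl_cm`).
#' @param response A [legacy_response()].
#' @return A list with `N` and `P` (kg/ha/yr), nonnegative and nondecreasing
#'   in water-table depth.
#' @export
legacy_export <- function(wtl_cm, fertility, response = legacy_response()) {
  if (any(!is.finite(wtl_cm))) stop_domain("wtl_cm must be finite")
  bad <- setdiff(unique(fertility), names(response$slopes_n))
  if (length(bad)) stop_config("unknown fertility class: ", bad[1L])
  excess <- pmax(0, wtl_cm - response$wtl0_cm)
  list(
    N = unname(response$slopes_n[fertility] * excess),
    P = unname(response$slopes_p[fertility] * excess)
  )
}
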