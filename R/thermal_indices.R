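#' Outdoor wet bulb globe temperature
#'
#' Composes the standard outdoor WBGT from its three component thermometer
#' readings: `0.7 * tnwb + 0.2 * tg + 0.1 * ta`. Being a convex combination,
#' the result always lies between the smallest and largest input.
#'
#' @param tnwb Natural wet-bulb temperature, degrees C.
#' @param tg Black-globe temperature, degrees C.
#' @param ta Air (dry-bulb) temperature, degrees C.
#' @return WBGT in degrees C (vectorised).
#' @examples
#' wbgt_outdoor(25, 35, 30) # 27.5
#' @export
wbgt_outdoor <- function(tnwb, tg, ta) {
  stopifnot(is.numeric(tnwb), is.numeric(tg), is.numeric(ta))
  0.7 * tnwb + 0.2 * tg + 0.1 * ta
}

#' Mean radiant temperature from a black-globe thermometer
#'
#' Standard forced-convection globe formula (globe thermometry as in ISO
#' 7726): the radiant field is recovered from the globe reading by adding the
#' convective exchange term
#' \deqn{T_{mrt} = \left[(T_g + 273.15)^4 +
#'   \frac{1.1\times10^8\, v^{0.6}}{\varepsilon D^{0.4}} (T_g - T_a)\right]^{1/4}
#'   - 273.15}
#' With no radiant load (`tg == ta`) the formula returns `ta` for any wind
#' speed.
#'
#' @param tg Black-globe temperature, degrees C.
#' @param ta Air temperature, degrees C.
#' @param wind Air speed at globe height, m/s.
#' @param globe_diameter Globe diameter in metres (default 0.15, the standard
#'   150 mm globe).
#' @param emissivity Globe emissivity (default 0.95, matt black).
#' @return Mean radiant temperature, degrees C (vectorised).
#' @export
mean_radiant_temperature <- function(tg, ta, wind, globe_diameter = 0.15,
                                     emissivity = 0.95) {
  if (any(globe_diameter <= 0)) {
    stop("`globe_diameter` must be positive (metres)", call. = FALSE)
  }
  if (any(wind < 0)) stop("`wind` must be non-negative", call. = FALSE)
  tg_k <- tg + 273.15
  rad4 <- tg_k^4 +
    1.1e8 * wind^0.6 / (emissivity * globe_diameter^0.4) * (tg - ta)
  # Strong convective cooling of a globe barely above air temperature can
  # drive the fourth-power balance negative; floor at absolute zero.
  rad4 <- pmax(rad4, 0)
  rad4^0.25 - 273.15
}

#' Saturation vapour pressure over water (Magnus form)
#'
#' Magnus formulation with the Alduchov-Eskridge coefficients,
#' `6.1094 * exp(17.625 * t / (243.04 + t))`. Agreement with the reference
#' (Hardy ITS-90) formulation is well under 0.05 kPa across the warm range
#' relevant to field heat-stress work.
#'
#' @param ta Air temperature, degrees C.
#' @return Saturation vapour pressure in hPa (vectorised).
#' @export
saturation_vapour_pressure <- function(ta) {
  6.1094 * exp(17.625 * ta / (243.04 + ta))
}

# Evaluate the UTCI offset polynomial. Inputs already clamped/validated.
.utci_offset <- function(ta, va, dtmrt, pa) {
  n <- length(ta)
  ta_p <- lapply(0:6, function(k) ta^k)
  va_p <- lapply(0:6, function(k) va^k)
  dt_p <- lapply(0:6, function(k) dtmrt^k)
  pa_p <- lapply(0:6, function(k) pa^k)
  out <- numeric(n)
  e <- .utci_poly_expo
  cf <- .utci_poly_coef
  for (r in seq_along(cf)) {
    out <- out + cf[r] *
      ta_p[[e[r, "ta"] + 1L]] * va_p[[e[r, "va"] + 1L]] *
      dt_p[[e[r, "dtmrt"] + 1L]] * pa_p[[e[r, "pa"] + 1L]]
  }
  out
}

#' Universal thermal climate index (UTCI)
#'
#' Equivalent temperature from the operational sixth-order polynomial
#' approximation to the UTCI-Fiala thermophysiological model. The polynomial
#' is a function of air temperature, wind speed at 10 m, the elevation of the
#' mean radiant temperature over air temperature, and water vapour pressure
#' (derived from relative humidity by [saturation_vapour_pressure()]).
#'
#' Inputs outside the polynomial's published validity envelope
#' (`ta` in \[-50, 50\] degC, `wind10` in \[0.5, 17\] m/s, `tmrt - ta` in
#' \[-30, 70\] degC, vapour pressure at most 5 kPa) are clamped to the
#' envelope with a warning rather than rejected: field wind speeds below
#' 0.5 m/s are common and would otherwise make whole shifts uncomputable.
#'
#' @param ta Air temperature, degrees C.
#' @param tmrt Mean radiant temperature, degrees C.
#' @param wind10 Wind speed at 10 m reference height, m/s.
#' @param rh Relative humidity, percent.
#' @return UTCI equivalent temperature in degrees C (vectorised).
#' @export
utci <- function(ta, tmrt, wind10, rh) {
  if (any(!is.finite(ta)) || any(!is.finite(tmrt)) ||
      any(!is.finite(wind10)) || any(!is.finite(rh))) {
    stop("non-finite inputs to utci()", call. = FALSE)
  }
  if (any(rh < 0 | rh > 100)) {
    stop("`rh` must be within [0, 100] percent", call. = FALSE)
  }
  n <- max(length(ta), length(tmrt), length(wind10), length(rh))
  ta <- rep_len(ta, n); tmrt <- rep_len(tmrt, n)
  wind10 <- rep_len(wind10, n); rh <- rep_len(rh, n)
  dtmrt <- tmrt - ta
  pa <- rh / 100 * saturation_vapour_pressure(ta) / 10  # kPa
  clamped <- ta < -50 | ta > 50 | wind10 < 0.5 | wind10 > 17 |
    dtmrt < -30 | dtmrt > 70 | pa > 5
  if (any(clamped)) {
    warning(sum(clamped), " input(s) outside the UTCI validity envelope; ",
            "clamped to the envelope", call. = FALSE)
  }
  ta_c <- pmin(pmax(ta, -50), 50)
  va_c <- pmin(pmax(wind10, 0.5), 17)
  dt_c <- pmin(pmax(dtmrt, -30), 70)
  pa_c <- pmin(pa, 5)
  ta_c + .utci_offset(ta_c, va_c, dt_c, pa_c)
}

#' Default WBGT risk-category band edges
#'
#' The five-band occupational heat-illness risk scale is not standardised to
#' single universal cut points; these defaults follow a common occupational
#' banding and every function taking categories accepts alternative edges.
#' Category k applies to WBGT in `[edges[k-1], edges[k])`.
#' @return Numeric vector of four ascending band edges (degrees C).
#' @export
wbgt_category_edges <- function() c(23, 25, 28, 30)

#' WBGT occupational risk category and heat-stress flag
#'
#' Ordinal risk category 1 (no risk) to 5 (extreme risk) from configurable
#' band edges, and the binary occupational heat-stress flag (WBGT above
#' 24.8 degrees C).
#'
#' @param wbgt WBGT, degrees C.
#' @param edges Four ascending band edges; see [wbgt_category_edges()].
#' @param flag_threshold Heat-stress flag threshold, degrees C (default 24.8).
#' @return Integer category 1-5 (vectorised). The heat-stress flag is
#'   available as attribute `"heat_stress"` and from [heat_stress_flag()].
#' @export
wbgt_category <- function(wbgt, edges = wbgt_category_edges(),
                          flag_threshold = 24.8) {
  stopifnot(length(edges) == 4, !is.unsorted(edges))
  if (any(!is.finite(wbgt))) stop("non-finite WBGT", call. = FALSE)
  cat <- findInterval(wbgt, edges) + 1L
  structure(cat, heat_stress = wbgt > flag_threshold)
}

#' Occupational heat-stress flag
#'
#' TRUE when WBGT exceeds the occupational threshold (default 24.8 degrees C).
#' @inheritParams wbgt_category
#' @return Logical vector.
#' @export
heat_stress_flag <- function(wbgt, flag_threshold = 24.8) {
  wbgt > flag_threshold
}

.utci_levels <- c(
  "extreme cold stress", "very strong cold stress", "strong cold stress",
  "moderate cold stress", "slight cold stress", "no thermal stress",
  "moderate heat stress", "strong heat stress", "very strong heat stress",
  "extreme heat stress"
)
.utci_breaks <- c(-40, -27, -13, 0, 9, 26, 32, 38, 46)

#' UTCI assessment-scale category
#'
#' Standard ten-class UTCI stress scale, from extreme cold stress to extreme
#' heat stress. "Extreme heat stress" applies strictly above 46 degrees C.
#'
#' @param utci UTCI equivalent temperature, degrees C.
#' @return Ordered factor with the ten assessment-scale labels.
#' @export
utci_category <- function(utci) {
  if (any(!is.finite(utci))) stop("non-finite UTCI", call. = FALSE)
  # bands are closed on the left (9 degC is already "no thermal stress"),
  # except that "extreme heat stress" requires strictly more than 46 degC
  idx <- findInterval(utci, .utci_breaks) + 1L
  idx[idx == 10L & utci <= 46] <- 9L
  factor(.utci_levels[idx], levels = .utci_levels, ordered = TRUE)
}

# Internal range/ordering checks for a shift's meteorological samples.
.check_meteo <- function(series) {
  need <- c("ta_c", "rh_pct", "tg_c", "tnwb_c", "wind_ms")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop("meteorology series is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(series) == 0) stop("empty meteorology series", call. = FALSE)
  if (any(series$rh_pct < 0 | series$rh_pct > 100)) {
    stop("relative humidity outside [0, 100]", call. = FALSE)
  }
  if (any(series$wind_ms < 0)) stop("negative wind speed", call. = FALSE)
  if (any(series$tg_c < series$ta_c - 5)) {
    stop("globe temperature more than 5 degC below air temperature",
         call. = FALSE)
  }
  if ("timestamp" %in% names(series) && nrow(series) > 1 &&
      is.unsorted(series$timestamp, strictly = TRUE)) {
    stop("timestamps must be strictly increasing within a visit",
         call. = FALSE)
  }
  invisible(series)
}

#' Summarise a shift's thermal exposure
#'
#' Computes WBGT (from the three component thermometers) and UTCI (via the
#' globe-derived mean radiant temperature and the polynomial) for every sample
#' of a working shift, then reduces to the per-visit mean and peak of each
#' index together with risk categories and the occupational heat-stress flag.
#'
#' Categories and the flag are assigned on the peak value by default, since
#' maximum exposure during a shift is what occupational limits address; set
#' `categorise_on = "mean"` for average-based categories.
#'
#' @param series Data frame of meteorological samples with columns `ta_c`,
#'   `rh_pct`, `tg_c`, `tnwb_c`, `wind_ms` and optionally `timestamp`.
#' @param categorise_on `"peak"` (default) or `"mean"`.
#' @param wind_height_factor Multiplier scaling instrument-height wind speed
#'   to the 10 m reference expected by the UTCI polynomial. Default 1.49, a
#'   neutral log-profile factor for a hand-held anemometer at about 1.5 m over
#'   short grass (roughness length 0.03 m).
#' @param wbgt_edges,flag_threshold Passed to [wbgt_category()].
#' @return One-row tibble: mean and peak of WBGT, UTCI, air temperature and
#'   relative humidity, plus `wbgt_category`, `utci_category` and
#'   `heat_stress_flag`.
#' @export
summarise_exposure <- function(series, categorise_on = c("peak", "mean"),
                               wind_height_factor = 1.49,
                               wbgt_edges = wbgt_category_edges(),
                               flag_threshold = 24.8) {
  categorise_on <- match.arg(categorise_on)
  .check_meteo(series)
  wbgt <- wbgt_outdoor(series$tnwb_c, series$tg_c, series$ta_c)
  tmrt <- mean_radiant_temperature(series$tg_c, series$ta_c, series$wind_ms)
  utci_v <- utci(series$ta_c, tmrt, series$wind_ms * wind_height_factor,
                 series$rh_pct)
  pick <- function(mean_v, peak_v) {
    if (categorise_on == "peak") peak_v else mean_v
  }
  wbgt_for_cat <- pick(mean(wbgt), max(wbgt))
  utci_for_cat <- pick(mean(utci_v), max(utci_v))
  tibble::tibble(
    wbgt_mean = mean(wbgt), wbgt_peak = max(wbgt),
    utci_mean = mean(utci_v), utci_peak = max(utci_v),
    ta_mean = mean(series$ta_c), ta_peak = max(series$ta_c),
    rh_mean = mean(series$rh_pct), rh_peak = max(series$rh_pct),
    wbgt_category = as.integer(
      wbgt_category(wbgt_for_cat, wbgt_edges, flag_threshold)),
    utci_category = utci_category(utci_for_cat),
    heat_stress_flag = heat_stress_flag(wbgt_for_cat, flag_threshold)
  )
}
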