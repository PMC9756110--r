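# PAEE calibration-equation coefficients (method A). Kept in one table so a
# corrected reading of any coefficient is a data change, not a code change.
# Terms: hras, hras x hras_3min, hras_3min, ln(rmssd), shr, intercept.
paee_coefficients <- c(
  hras = 5, hras_x_hras3 = 0.23, hras3 = 2.2,
  log_rmssd = 9.2, shr = -2.6, intercept = -82
)

#' Tympanic temperature from duplicate measurements
#'
#' Duplicate readings are taken from both tympanic membranes at each
#' timepoint; the recorded value is the highest available reading (infrared
#' tympanic thermometry under-reads with poor probe placement, so the maximum
#' is the best estimate of the true value).
#'
#' @param readings Numeric vector of tympanic readings, degrees C (typically
#'   four: two per membrane). `NA`s are ignored.
#' @return Highest available reading, degrees C.
#' @export
tympanic_measurement <- function(readings) {
  readings <- readings[is.finite(readings)]
  if (length(readings) == 0) {
    stop("no usable tympanic readings", call. = FALSE)
  }
  max(readings)
}

.check_baseline <- function(t_tymp0, hr0) {
  if (any(!is.finite(t_tymp0)) || any(!is.finite(hr0))) {
    stop("non-finite baseline values", call. = FALSE)
  }
  if (any(t_tymp0 >= 39.5) || any(t_tymp0 < 34)) {
    stop("baseline tympanic temperature must lie in [34, 39.5) degC ",
         "(the 39.5 degC ceiling must exceed baseline)", call. = FALSE)
  }
  if (any(hr0 >= 180) || any(hr0 < 30)) {
    stop("resting heart rate must lie in [30, 180) bpm ",
         "(the 180 bpm ceiling must exceed baseline)", call. = FALSE)
  }
  invisible(NULL)
}

#' Modified physiological strain index (skin-temperature form)
#'
#' Heat-strain score on a nominal 0-10 scale combining the normalised
#' elevation of chest skin temperature over the baseline tympanic temperature
#' and of heart rate over the resting value:
#' \deqn{PSI = 5\frac{T_{skt} - T_{tymp0}}{39.5 - T_{tymp0}} +
#'             5\frac{HR_t - HR_0}{180 - HR_0}}
#' The chest-skin form substitutes skin temperature for core temperature
#' (against a tympanic baseline) where core telemetry is unavailable. Values
#' are deliberately not clamped: negative values (skin below the tympanic
#' baseline) and values above 10 are preserved, because downstream models use
#' the index as a continuous exposure; out-of-scale values are flagged via
#' attribute `"out_of_scale"`.
#'
#' @param t_skt Chest skin temperature at time t, degrees C.
#' @param t_tymp0 Baseline tympanic temperature, degrees C (below 39.5).
#' @param hr_t Heart rate at time t, bpm.
#' @param hr0 Resting heart rate, bpm (below 180).
#' @return PSI value(s), vectorised; attribute `"out_of_scale"` marks values
#'   outside \[0, 10\].
#' @examples
#' psi_mod(38, 37, 130, 80) # 4.5
#' @export
psi_mod <- function(t_skt, t_tymp0, hr_t, hr0) {
  .check_baseline(t_tymp0, hr0)
  psi <- 5 * (t_skt - t_tymp0) / (39.5 - t_tymp0) +
    5 * (hr_t - hr0) / (180 - hr0)
  structure(psi, out_of_scale = psi < 0 | psi > 10)
}

#' PSI over a shift's physiology series
#'
#' Applies [psi_mod()] elementwise to a shift's wearable samples and reduces
#' to the per-sample series, its arithmetic mean and its peak.
#'
#' @param samples Data frame with columns `tskin_c` and `hr_bpm` (and
#'   optionally `timestamp`, used only for ordering checks).
#' @param t_tymp0,hr0 Baseline tympanic temperature (degC) and resting heart
#'   rate (bpm).
#' @return List with elements `psi` (numeric vector), `mean_psi`, `peak_psi`.
#' @export
psi_series <- function(samples, t_tymp0, hr0) {
  if (nrow(samples) == 0) stop("empty physiology series", call. = FALSE)
  if ("timestamp" %in% names(samples) && nrow(samples) > 1 &&
      is.unsorted(samples$timestamp, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  psi <- as.numeric(psi_mod(samples$tskin_c, t_tymp0, samples$hr_bpm, hr0))
  list(psi = psi, mean_psi = mean(psi), peak_psi = max(psi))
}

#' Physical activity energy expenditure from heart-rate features (method A)
#'
#' Calibration equation on wearable heart-rate features:
#' `5*HRaS + 0.23*HRaS*HRaS_3min + 2.2*HRaS_3min + 9.2*ln(RMSSD) - 2.6*SHR - 82`.
#' The natural logarithm is used. Raw negative outputs (possible at rest with
#' low heart-rate variability) are floored at zero and flagged; the raw value
#' is kept in attribute `"raw"`.
#'
#' @param hras Heart rate above sleeping/resting heart rate, bpm.
#' @param hras_3min Average heart rate above resting at 3 min into the
#'   walk-test calibration, bpm.
#' @param rmssd Root mean square of successive inter-beat-interval
#'   differences during calibration, ms (must be positive).
#' @param shr Sleeping/resting heart rate, bpm.
#' @return PAEE (non-negative), with attributes `"raw"` and `"floored"`.
#' @export
paee_method_a <- function(hras, hras_3min, rmssd, shr) {
  if (any(rmssd <= 0)) stop("`rmssd` must be positive", call. = FALSE)
  if (any(hras < 0)) stop("`hras` must be non-negative", call. = FALSE)
  if (any(shr <= 0)) stop("`shr` must be positive", call. = FALSE)
  k <- paee_coefficients
  raw <- k[["hras"]] * hras + k[["hras_x_hras3"]] * hras * hras_3min +
    k[["hras3"]] * hras_3min + k[["log_rmssd"]] * log(rmssd) +
    k[["shr"]] * shr + k[["intercept"]]
  structure(pmax(raw, 0), raw = raw, floored = raw < 0)
}

#' Time-weighted METs from an observed activity log (method B)
#'
#' Matches direct activity observations to a task-to-MET lookup (historic
#' indirect-calorimetry values by task) and returns the time-weighted mean
#' MET over the log.
#'
#' @param activity_log Data frame with columns `task` and `minutes`.
#' @param lookup Data frame with columns `task` and `met`; defaults to
#'   [default_met_table()].
#' @return Time-weighted mean MET.
#' @export
mets_method_b <- function(activity_log, lookup = default_met_table()) {
  if (is.null(activity_log) || nrow(activity_log) == 0) {
    stop("empty activity log", call. = FALSE)
  }
  if (any(activity_log$minutes <= 0)) {
    stop("activity minutes must be positive", call. = FALSE)
  }
  idx <- match(activity_log$task, lookup$task)
  if (anyNA(idx)) {
    stop("unknown task label(s): ",
         paste(unique(activity_log$task[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  stats::weighted.mean(lookup$met[idx], activity_log$minutes)
}

#' Reconcile wearable and observational METs estimates
#'
#' The wearable (method A) estimate is used when it lies in the expected
#' range of 2-15 METs (bounds inclusive); otherwise the observational
#' (method B) estimate replaces it. Provenance records which method supplied
#' the final value.
#'
#' @param mets_a Wearable-derived METs (method A).
#' @param mets_b Observation-derived METs (method B); may be `NA` when no
#'   activity log exists.
#' @param range Acceptance range for method A (default `c(2, 15)`).
#' @return List with `mets` and `provenance` (`"A"` or `"B"`).
#' @export
mets_reconcile <- function(mets_a, mets_b, range = c(2, 15)) {
  a_ok <- is.finite(mets_a) & mets_a >= range[1] & mets_a <= range[2]
  if (!a_ok && !is.finite(mets_b)) {
    stop("method A outside the expected range and no method B estimate",
         call. = FALSE)
  }
  list(mets = if (a_ok) mets_a else mets_b,
       provenance = if (a_ok) "A" else "B")
}

#' Default task-to-MET lookup table
#'
#' Synthetic default lookup for common agricultural and domestic tasks, in
#' line with published MET ranges for moderate manual work. These are
#' editable stand-ins, not measured calorimetry values; replace with a
#' study-specific table via the `lookup` argument of [mets_method_b()].
#'
#' @return Tibble with columns `task` and `met`.
#' @export
default_met_table <- function() {
  path <- system.file("extdata", "task_met_table_synthetic.csv",
                      package = "heatstrain")
  if (nzchar(path)) {
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  } else {
    # fallback when running from a source checkout
    tibble::tibble(
      task = c("rest", "cooking", "washing_clothes", "walking",
               "water_collection", "gardening", "rice_planting",
               "harvesting", "firewood_collection"),
      met = c(1.3, 2.0, 3.5, 3.3, 5.0, 4.0, 4.5, 4.0, 4.8)
    )
  }
}
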