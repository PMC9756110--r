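#' Umbilical artery resistance index
#'
#' `(systolic - diastolic) / systolic` from Doppler velocities; ranges from 0
#' (no systolic-diastolic differential) to 1 (absent end-diastolic flow).
#' Higher values indicate greater placental vascular resistance.
#'
#' @param systolic Systolic velocity, cm/s (positive).
#' @param diastolic Diastolic velocity, cm/s (between 0 and `systolic`).
#' @return Resistance index in \[0, 1\] (vectorised).
#' @examples
#' resistance_index(60, 15) # 0.75
#' @export
resistance_index <- function(systolic, diastolic) {
  if (any(systolic <= 0)) {
    stop("systolic velocity must be positive", call. = FALSE)
  }
  if (any(diastolic < 0 | diastolic > systolic)) {
    stop("diastolic velocity must lie in [0, systolic]", call. = FALSE)
  }
  (systolic - diastolic) / systolic
}

#' Combine duplicate resistance-index readings
#'
#' The resistance index is recorded twice at each timepoint and each trace is
#' quality-assessed; the recorded value is the mean over quality-passing
#' readings (duplicates agree closely when both pass, so the mean is a
#' low-variance unbiased combination).
#'
#' @param ri Numeric vector of resistance-index readings.
#' @param quality_ok Logical vector, same length: did the trace pass quality
#'   assessment?
#' @return Mean RI over quality-passing readings.
#' @export
ri_from_duplicates <- function(ri, quality_ok) {
  stopifnot(length(ri) == length(quality_ok))
  keep <- which(quality_ok & is.finite(ri))
  if (length(keep) == 0) {
    stop("no quality-passing resistance-index readings", call. = FALSE)
  }
  mean(ri[keep])
}

#' Default gestational-age-indexed RI category thresholds
#'
#' Upper limit of normal umbilical artery RI by completed gestational week.
#' This is a synthetic stand-in reference curve (RI declines roughly linearly
#' over the third trimester as placental impedance falls); portable-Doppler
#' devices ship proprietary category bands, so the table is editable data,
#' not a clinical reference.
#'
#' @return Tibble with columns `ga_week` and `upper_normal_ri`.
#' @export
default_ri_table <- function() {
  path <- system.file("extdata", "ri_category_table_synthetic.csv",
                      package = "heatstrain")
  if (nzchar(path)) {
    tibble::as_tibble(utils::read.csv(path))
  } else {
    tibble::tibble(ga_week = 20:42,
                   upper_normal_ri = round(0.97 - 0.0085 * (20:42), 4))
  }
}

.ri_levels <- c("normal", "raised", "severely raised",
                "absent end-diastolic flow")

#' Umbilical artery RI risk category
#'
#' Ordinal risk label from a gestational-age-indexed threshold table:
#' `normal` below the GA-specific upper limit, `raised` at or above it,
#' `severely raised` at or above the limit plus `severe_margin`, and
#' `absent end-diastolic flow` at RI = 1.
#'
#' @param ri Resistance index in \[0, 1\].
#' @param ga_weeks Gestational age, weeks (within the table's range).
#' @param table Threshold table; defaults to [default_ri_table()].
#' @param severe_margin RI excess over the upper limit that marks the
#'   severely-raised band (default 0.10).
#' @return Ordered factor with the four risk labels (vectorised).
#' @export
ri_category <- function(ri, ga_weeks, table = default_ri_table(),
                        severe_margin = 0.10) {
  if (any(ri < 0 | ri > 1)) stop("RI must lie in [0, 1]", call. = FALSE)
  if (any(ga_weeks < min(table$ga_week) | ga_weeks > max(table$ga_week))) {
    stop("gestational age outside the RI threshold table range (",
         min(table$ga_week), "-", max(table$ga_week), " weeks)",
         call. = FALSE)
  }
  upper <- stats::approx(table$ga_week, table$upper_normal_ri,
                         xout = ga_weeks, rule = 2)$y
  n <- max(length(ri), length(upper))
  ri <- rep_len(ri, n); upper <- rep_len(upper, n)
  lab <- ifelse(ri >= 1, .ri_levels[4],
         ifelse(ri >= upper + severe_margin, .ri_levels[3],
         ifelse(ri >= upper, .ri_levels[2], .ri_levels[1])))
  factor(lab, levels = .ri_levels, ordered = TRUE)
}

#' Sustained fetal heart rate threshold crossing
#'
#' TRUE when some contiguous window of at least `window_min` minutes has all
#' samples at or above 160 bpm (tachycardia) or all at or below 115 bpm
#' (bradycardia). The sustained-window rule is applied to both arms by
#' default for conservatism; `instant_tachy = TRUE` instead calls any single
#' sample at or above 160 a positive (the tachycardia clause read without the
#' duration qualifier).
#'
#' A series spanning less than `window_min` minutes cannot support a negative
#' call; the result then carries attribute `indeterminate = TRUE`.
#'
#' @param fhr Numeric vector of FHR samples, bpm.
#' @param time_min Sample times in minutes from the start of the recording
#'   (strictly increasing, same length as `fhr`).
#' @param tachy_bpm,brady_bpm Thresholds, default 160 and 115 (inclusive).
#' @param window_min Sustained-window length in minutes (default 5).
#' @param instant_tachy Call tachycardia on any single sample (default FALSE).
#' @return Logical scalar with attributes `trigger` (`"tachycardia"`,
#'   `"bradycardia"` or `NA`) and `indeterminate`.
#' @export
fhr_strain <- function(fhr, time_min, tachy_bpm = 160, brady_bpm = 115,
                       window_min = 5, instant_tachy = FALSE) {
  if (length(fhr) == 0) stop("empty FHR series", call. = FALSE)
  stopifnot(length(fhr) == length(time_min))
  if (length(time_min) > 1 && is.unsorted(time_min, strictly = TRUE)) {
    stop("FHR sample times must be strictly increasing", call. = FALSE)
  }
  span <- diff(range(time_min))
  sustained <- function(flag) {
    # any run of consecutive flagged samples spanning >= window_min minutes
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (time_min[ends[k]] - time_min[starts[k]] >= window_min) return(TRUE)
    }
    FALSE
  }
  tachy <- if (instant_tachy) any(fhr >= tachy_bpm) else
    sustained(fhr >= tachy_bpm)
  brady <- sustained(fhr <= brady_bpm)
  out <- tachy || brady
  trigger <- if (tachy) "tachycardia" else if (brady) "bradycardia" else
    NA_character_
  structure(out, trigger = trigger,
            indeterminate = !out && span < window_min)
}

#' Composite fetal strain outcome
#'
#' Fetal strain at a working-period timepoint is the disjunction of a
#' sustained FHR threshold crossing ([fhr_strain()]) and an increase in the
#' umbilical artery RI risk category from the visit's baseline
#' ([ri_category()]). Participants below 28 completed weeks are not eligible
#' for Doppler assessment, and the outcome is then FHR-only.
#'
#' @param fhr,time_min Working-period FHR series; see [fhr_strain()].
#' @param ri_now Working-period resistance index, or `NA` when not measured.
#' @param ri_baseline Baseline resistance index (required whenever `ri_now`
#'   is present).
#' @param ga_weeks Gestational age in weeks.
#' @param ri_table Threshold table for [ri_category()].
#' @param ri_eligible_weeks Doppler eligibility gate (default 28 weeks).
#' @param ... Passed on to [fhr_strain()].
#' @return List with logical `fhr_strain`, `ri_strain`, `fetal_strain` and
#'   character `trigger` (`"FHR"`, `"RI"`, `"FHR+RI"` or `NA`).
#' @export
fetal_strain <- function(fhr, time_min, ri_now = NA, ri_baseline = NA,
                         ga_weeks, ri_table = default_ri_table(),
                         ri_eligible_weeks = 28, ...) {
  f <- fhr_strain(fhr, time_min, ...)
  ri_used <- is.finite(ri_now) && ga_weeks >= ri_eligible_weeks
  if (ri_used && !is.finite(ri_baseline)) {
    stop("baseline RI required when a working-period RI is observed",
         call. = FALSE)
  }
  ri_pos <- if (ri_used) {
    ri_category(ri_now, ga_weeks, ri_table) >
      ri_category(ri_baseline, ga_weeks, ri_table)
  } else {
    FALSE
  }
  any_strain <- as.logical(f) || ri_pos
  trigger <- if (as.logical(f) && ri_pos) "FHR+RI" else
    if (as.logical(f)) "FHR" else if (ri_pos) "RI" else NA_character_
  list(fhr_strain = as.logical(f), ri_strain = ri_pos,
       fetal_strain = any_strain, trigger = trigger,
       fhr_trigger = attr(f, "trigger"),
       indeterminate = attr(f, "indeterminate"))
}
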