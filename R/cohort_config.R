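#' Configuration for the synthetic cohort generator
#'
#' Returns the full generator configuration as a validated list. The
#' defaults define the reference study conditions the generator emulates: a
#' cohort of pregnant agricultural workers observed over one or two working
#' shifts spanning a hot rainy season and a hot-dry season, with meteorology
#' calibrated so that downstream WBGT/UTCI summaries, maternal strain and
#' fetal outcomes reproduce the field summaries the generator is benchmarked
#' against (air temperature mean 33.5 degC, humidity mean 28.1%, WBGT mean
#' 27.2 degC, UTCI mean 34.0 degC, mean peak PSI 5.1, baseline fetal heart
#' rate 125 bpm, working fetal heart rate 147 bpm, 34% of working episodes
#' strained). Any element can be overridden by name.
#'
#' The generative structure is mediated: heat stress raises maternal heart
#' rate and skin temperature (hence PSI); fetal heart rate responds linearly
#' to heat stress and PSI; latent fetal-strain events follow a logistic model
#' with a direct heat-stress effect and a PSI effect, manifesting either as a
#' sustained FHR excursion or (when Doppler-eligible) as an umbilical RI
#' category increase.
#'
#' @param ... Named overrides of any top-level or nested default (nested
#'   lists are replaced element-wise).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_participants = 92L,
    second_visit_fraction = 0.33,
    shift_hours = 8L,
    samples_per_hour = 12L,
    seed = 1L,
    ri_eligible_weeks = 28,
    exposure_basis = "mean",        # "peak" uses peak-to-timepoint exposure
    symptom_prob = 0.58,            # cosmetic; unused by any model
    meteo_params = list(
      season_mix = 0.5,             # probability a visit falls in the dry season
      ta_mean = c(rainy = 31.5, dry = 35.5),  # shift-mean air temp, degC
      ta_between_sd = 3.0,          # day-to-day SD of the shift mean
      ta_diurnal_amp = 3.2,         # morning-to-afternoon rise amplitude
      ta_within_sd = 0.6,           # sample-level noise
      rh_mean = c(rainy = 46, dry = 6),       # shift-mean relative humidity, %
      rh_between_sd = 16,
      rh_within_sd = 4,
      rh_ta_coupling = 1.5,         # % RH lost per degC of within-shift warming
      wind_meanlog = log(1.08), wind_sdlog = 0.45, # m/s at instrument height
      solar_mean = 0.35, solar_sd = 0.20,     # mean solar load factor, [0,1]
      solar_within_sd = 0.10,
      globe_gain = 10,              # globe excess at full sun, no wind, degC
      nwb_gain = 12.8               # natural-wet-bulb excess at full sun, degC
    ),
    strain_link = list(
      tymp0_mean = 36.9, tymp0_sd = 0.3,      # baseline tympanic, degC
      hr0_mean = 82, hr0_sd = 9,              # resting heart rate, bpm
      tskin_intercept = 32.66,      # working chest skin temp at UTCI = 0
      tskin_slope = 0.13,           # degC skin per degC UTCI
      tskin_participant_sd = 0.55,
      tskin_sd = 0.35,
      hr_intercept = 52.3,          # working HR at UTCI = 0, bpm
      hr_slope = 2.4,               # bpm per degC UTCI
      hr_participant_sd = 10,
      hr_visit_sd = 16,             # task-intensity variation between visits
      hr_sd = 6,
      tskin_visit_sd = 0.65
    ),
    fhr_params = list(
      baseline_mean = 125, baseline_sd = 7.9,  # resting FHR level, bpm
      work_shift = 21.2,            # working-period FHR increment at refs
      stress_slope = 1.18,          # bpm per degC heat stress (direct)
      psi_effect = 0.80,            # bpm per PSI unit
      noise_sd = 3,                 # episode-level noise
      series_sd = 2.5,              # within-series sample noise
      tachy_excursion = 13, brady_excursion = 30,  # FHR-manifest strain shifts
      tachy_level = 161, brady_level = 112,    # guaranteed excursion bounds
      stress_ref = 34, psi_ref = 3.5           # centring constants
    ),
    strain_logit = list(
      intercept = -0.64,            # logit of episode strain risk at refs
      stress_lor = log(1.12),       # direct log-OR per degC heat stress
      psi_lor = log(1.20),          # log-OR per PSI unit
      re_sd = 0.3,                  # participant random-intercept SD (logit)
      stress_ref = 34, psi_ref = 3.5,
      p_ri_manifest = 0.6,          # strain shows as RI change when eligible
      p_brady = 0.2                 # FHR-manifest strain that is bradycardic
    ),
    ri_params = list(
      baseline_intercept = 1.10,    # baseline RI at GA 0 (linear decline)
      baseline_ga_slope = -0.016,   # RI per gestational week
      baseline_sd = 0.05,
      work_jitter_sd = 0.02,        # non-strain working-period RI jitter
      raised_sd = 0.03              # spread of strained RI above threshold
    ),
    covariate_params = list(
      ga_mean = 26.5, ga_sd = 5, ga_min = 16, ga_max = 34,  # weeks, visit 1
      second_visit_gap_weeks = 8,
      age_meanlog = log(28), age_sdlog = 0.28,
      fat_mass_mean = 29.8, fat_mass_sd = 5.5,
      fat_mass_min = 15, fat_mass_max = 50,
      walk_mean = 450, walk_sd = 60, walk_min = 250, walk_max = 700
    )
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown configuration field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(dots)) {
      if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
        bad2 <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
        if (length(bad2)) {
          stop("unknown configuration field(s) in `", nm, "`: ",
               paste(bad2, collapse = ", "), call. = FALSE)
        }
        cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
      } else {
        cfg[[nm]] <- dots[[nm]]
      }
    }
  }
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid configuration field `", field, "`: ", msg,
                  call. = FALSE)
  }
  chk(is.numeric(cfg$n_participants) && cfg$n_participants >= 1,
      "n_participants", "must be a positive count")
  chk(cfg$second_visit_fraction >= 0 && cfg$second_visit_fraction <= 1,
      "second_visit_fraction", "must be a probability in [0, 1]")
  chk(cfg$shift_hours >= 1, "shift_hours", "must be at least 1")
  chk(cfg$samples_per_hour >= 1, "samples_per_hour", "must be at least 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a single integer")
  chk(cfg$exposure_basis %in% c("mean", "peak"), "exposure_basis",
      "must be \"mean\" or \"peak\"")
  sds <- c(
    meteo_params = cfg$meteo_params[c("ta_between_sd", "ta_within_sd",
                                      "rh_between_sd", "rh_within_sd",
                                      "wind_sdlog")],
    strain_link = cfg$strain_link[c("tymp0_sd", "hr0_sd")],
    fhr_params = cfg$fhr_params[c("baseline_sd", "series_sd")])
  # zero is allowed so that noise-free configurations can exercise the
  # deterministic skeleton of the generator
  for (nm in names(sds)) {
    chk(sds[[nm]] >= 0, nm, "SD must be non-negative")
  }
  chk(cfg$strain_logit$p_ri_manifest >= 0 && cfg$strain_logit$p_ri_manifest <= 1,
      "strain_logit$p_ri_manifest", "must be a probability in [0, 1]")
  chk(cfg$strain_logit$p_brady >= 0 && cfg$strain_logit$p_brady <= 1,
      "strain_logit$p_brady", "must be a probability in [0, 1]")
  chk(cfg$symptom_prob >= 0 && cfg$symptom_prob <= 1, "symptom_prob",
      "must be a probability in [0, 1]")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d participants, second-visit fraction %.2f, %d h shifts ",
              x$n_participants, x$second_visit_fraction, x$shift_hours))
  cat(sprintf("(%d samples/h), seed %d\n", x$samples_per_hour,
              as.integer(x$seed)))
  cat(sprintf("  strain logistic: intercept %.3f, direct log-OR %.4f/degC, ",
              x$strain_logit$intercept, x$strain_logit$stress_lor))
  cat(sprintf("PSI log-OR %.4f\n", x$strain_logit$psi_lor))
  invisible(x)
}
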