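# Psychrometric wet-bulb temperature from air temperature and relative
# humidity (Stull 2011 empirical fit, valid for RH roughly 5-99%).
.stull_wet_bulb <- function(ta, rh) {
  rh <- pmin(pmax(rh, 5), 99)
  ta * atan(0.151977 * sqrt(rh + 8.313659)) + atan(ta + rh) -
    atan(rh - 1.676331) + 0.00391838 * rh^1.5 * atan(0.023101 * rh) -
    4.686035
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Per-sample UTCI for a generated meteorology table; wind speeds below the
# polynomial's 0.5 m/s floor are common in field data and are clamped
# silently here (the user-facing utci() warns instead).
.sample_utci <- function(meteo, wind_height_factor = 1.49) {
  tmrt <- mean_radiant_temperature(meteo$tg_c, meteo$ta_c, meteo$wind_ms)
  suppressWarnings(
    utci(meteo$ta_c, tmrt, meteo$wind_ms * wind_height_factor, meteo$rh_pct))
}

#' Generate shift meteorology for one or more visits
#'
#' Simulates a working shift's meteorological samples for `n_visits` visits
#' of the given season(s): air temperature with a between-visit level, a
#' morning-to-afternoon diurnal rise and sample noise; relative humidity
#' anti-coupled to the within-shift warming; lognormal wind; and a per-visit
#' solar load factor from which globe temperature (air temperature plus a
#' wind-damped solar excess) and natural wet-bulb temperature (psychrometric
#' wet bulb plus a solar excess, capped at air temperature) are derived.
#' Only the downstream WBGT/UTCI summaries are calibrated; the component
#' links are simple documented empirical forms.
#'
#' @param config A [cohort_config()].
#' @param season `"rainy"` or `"dry"`; scalar or one value per visit.
#' @param n_visits Number of visits to simulate.
#' @return Tibble with columns `visit`, `t_hours`, `ta_c`, `rh_pct`, `tg_c`,
#'   `tnwb_c`, `wind_ms`.
#' @export
generate_meteorology <- function(config, season = "dry", n_visits = 1) {
  mp <- config$meteo_params
  if (!all(season %in% c("rainy", "dry"))) {
    stop("unknown season label; use \"rainy\" or \"dry\"", call. = FALSE)
  }
  season <- rep_len(season, n_visits)
  H <- config$shift_hours
  ns <- H * config$samples_per_hour
  t_hours <- seq_len(ns) / config$samples_per_hour
  prof <- sin(pi * t_hours / (H * 1.1))
  prof <- prof - mean(prof)            # centred diurnal profile

  n <- n_visits * ns
  vis <- rep(seq_len(n_visits), each = ns)
  prof_s <- rep(prof, n_visits)
  ta_base <- stats::rnorm(n_visits, mp$ta_mean[season], mp$ta_between_sd)
  ta <- ta_base[vis] + mp$ta_diurnal_amp * prof_s +
    stats::rnorm(n, 0, mp$ta_within_sd)
  rh_base <- .rtrunc_norm(n_visits, mp$rh_mean[season], mp$rh_between_sd,
                          2, 97)
  rh <- pmin(pmax(rh_base[vis] - mp$rh_ta_coupling * mp$ta_diurnal_amp *
                    prof_s + stats::rnorm(n, 0, mp$rh_within_sd), 0.5), 100)
  wind <- pmin(pmax(stats::rlnorm(n, mp$wind_meanlog, mp$wind_sdlog),
                    0.1), 12)
  solar_v <- .rtrunc_norm(n_visits, mp$solar_mean, mp$solar_sd, 0.05, 1)
  solar <- pmin(pmax(solar_v[vis] + stats::rnorm(n, 0, mp$solar_within_sd),
                     0), 1)
  tg <- ta + mp$globe_gain * solar / (1 + 0.7 * wind)
  tnwb <- pmin(.stull_wet_bulb(ta, rh) + mp$nwb_gain * solar, ta)
  tibble::tibble(visit = vis, t_hours = rep(t_hours, n_visits),
                 ta_c = ta, rh_pct = rh, tg_c = tg, tnwb_c = tnwb,
                 wind_ms = wind)
}

#' Generate maternal physiology for generated shift meteorology
#'
#' Draws per-visit baselines (tympanic temperature and resting heart rate),
#' then simulates working-period heart rate and chest skin temperature as
#' linear responses to the per-sample UTCI plus participant-level,
#' visit-level and sample-level noise, and scores the modified PSI series
#' with [psi_series()].
#'
#' @param config A [cohort_config()].
#' @param meteo Meteorology from [generate_meteorology()].
#' @param b_hr,b_skin Optional per-visit participant effects (bpm, degC);
#'   default freshly drawn per visit from the configured participant SDs.
#' @return List with `baselines` (per-visit tympanic and resting HR),
#'   `series` (per-sample `hr_bpm`, `tskin_c`, `utci_c`, `psi`).
#' @export
generate_physiology <- function(config, meteo, b_hr = NULL, b_skin = NULL) {
  sl <- config$strain_link
  visits <- unique(meteo$visit)
  nv <- length(visits)
  vis_idx <- match(meteo$visit, visits)
  u <- .sample_utci(meteo)
  tymp0 <- .rtrunc_norm(nv, sl$tymp0_mean, sl$tymp0_sd, 36, 38)
  hr0 <- .rtrunc_norm(nv, sl$hr0_mean, sl$hr0_sd, 55, 115)
  if (is.null(b_hr)) b_hr <- stats::rnorm(nv, 0, sl$hr_participant_sd)
  if (is.null(b_skin)) b_skin <- stats::rnorm(nv, 0, sl$tskin_participant_sd)
  v_hr <- stats::rnorm(nv, 0, sl$hr_visit_sd)
  v_skin <- stats::rnorm(nv, 0, sl$tskin_visit_sd)
  n <- nrow(meteo)
  hr <- pmin(pmax(sl$hr_intercept + sl$hr_slope * u +
                    (b_hr + v_hr)[vis_idx] + stats::rnorm(n, 0, sl$hr_sd),
                  45), 175)
  tskin <- pmin(pmax(sl$tskin_intercept + sl$tskin_slope * u +
                       (b_skin + v_skin)[vis_idx] +
                       stats::rnorm(n, 0, sl$tskin_sd), 30), 39.4)
  psi <- as.numeric(psi_mod(tskin, tymp0[vis_idx], hr, hr0[vis_idx]))
  list(
    baselines = tibble::tibble(visit = visits, tymp_c = tymp0,
                               hr0_bpm = hr0),
    series = tibble::tibble(visit = meteo$visit, t_hours = meteo$t_hours,
                            hr_bpm = hr, tskin_c = tskin, utci_c = u,
                            psi = psi)
  )
}

# FHR series sampling grid (minutes) and the positions of the "reactivity"
# samples that break any would-be sustained threshold run in non-strain
# episodes (normal FHR traces show accelerations/returns, so an unstressed
# fetus does not hold >=160 or <=115 for a full 5 minutes).
.fhr_times <- seq(0, 6.5, by = 0.5)
.fhr_guard <- seq(5, length(.fhr_times), by = 5)

.make_fhr_series <- function(level, kind, series_sd) {
  # level: episode-level mean FHR; kind: "none", "tachy", "brady"
  ns <- length(.fhr_times)
  n_ep <- length(level)
  lev <- rep(level, each = ns)
  x <- lev + stats::rnorm(n_ep * ns, 0, series_sd)
  kind_s <- rep(kind, each = ns)
  guard <- rep(seq_len(ns) %in% .fhr_guard, n_ep)
  g <- guard & kind_s == "none"
  if (any(g)) {
    x[g] <- pmin(pmax(pmin(lev[g], 156) + stats::rnorm(sum(g), 0, series_sd),
                      117), 158)
  }
  tach <- kind_s == "tachy"
  if (any(tach)) x[tach] <- pmax(x[tach], 161)
  brad <- kind_s == "brady"
  if (any(brad)) x[brad] <- pmin(x[brad], 114)
  pmin(pmax(x, 55), 240)
}

# Working-period RI targets honouring the latent strain route.
# Returns values kept >= 0.01 away from every category threshold so that
# duplicate-reading jitter cannot flip the classification.
.ri_away_from_thresholds <- function(ri, upper, margin = 0.01) {
  for (thr in list(upper, upper + 0.1, rep(1, length(upper)))) {
    near <- !is.na(ri) & abs(ri - thr) < margin
    ri[near] <- thr[near] - margin
  }
  pmin(pmax(ri, 0.05), 1)
}

#' Generate fetal observations for generated exposures and strain
#'
#' Implements the structural fetal model: the baseline fetal heart rate is
#' drawn per visit; at each working timepoint the FHR level responds
#' linearly to heat stress and maternal PSI; a latent fetal-strain event is
#' drawn from a logistic model with a direct heat-stress effect, a PSI
#' effect and a participant random intercept; strain manifests either as a
#' sustained FHR excursion (tachycardic or bradycardic) or, in
#' Doppler-eligible visits, as an umbilical RI category increase tied to the
#' same latent event. Non-strain FHR traces include periodic reactivity
#' samples that preclude a sustained threshold crossing, and non-strain RI
#' values stay within the baseline category, so the composite classifier
#' recovers the latent event exactly.
#'
#' @param config A [cohort_config()].
#' @param visits Tibble with one row per visit: `visit`, `ga_weeks`,
#'   `b_strain` (participant logit random effect).
#' @param episodes Tibble with one row per working timepoint: `visit`,
#'   `timepoint` (`"mid"`/`"end"`), `utci`, `psi` (exposure and strain up to
#'   the timepoint), `ga_weeks`.
#' @param ri_table RI category thresholds ([default_ri_table()]).
#' @return List with `fetal` (per-timepoint summary rows incl. duplicate
#'   Doppler readings), `fhr_series` (long FHR samples) and `truth` (latent
#'   strain probabilities, events and manifestation routes).
#' @export
generate_fetal <- function(config, visits, episodes,
                           ri_table = default_ri_table()) {
  fp <- config$fhr_params
  slg <- config$strain_logit
  rp <- config$ri_params
  if (anyNA(episodes$utci) || anyNA(episodes$psi)) {
    stop("missing exposure or strain for a timepoint", call. = FALSE)
  }
  nv <- nrow(visits)
  n_ep <- nrow(episodes)
  vi <- match(episodes$visit, visits$visit)

  # baseline FHR level and baseline RI per visit
  fhr_base <- stats::rnorm(nv, fp$baseline_mean, fp$baseline_sd)
  eligible <- visits$ga_weeks >= config$ri_eligible_weeks
  upper_v <- stats::approx(ri_table$ga_week, ri_table$upper_normal_ri,
                           xout = pmin(pmax(visits$ga_weeks,
                                            min(ri_table$ga_week)),
                                       max(ri_table$ga_week)),
                           rule = 2)$y
  ri_base <- .ri_away_from_thresholds(
    stats::rnorm(nv, rp$baseline_intercept +
                   rp$baseline_ga_slope * visits$ga_weeks, rp$baseline_sd),
    upper_v)
  ri_base[!eligible] <- NA_real_

  # latent strain and manifestation route
  p <- stats::plogis(slg$intercept +
                       slg$stress_lor * (episodes$utci - slg$stress_ref) +
                       slg$psi_lor * (episodes$psi - slg$psi_ref) +
                       visits$b_strain[vi])
  strain <- stats::runif(n_ep) < p
  elig_ep <- eligible[vi]
  ri_route <- strain & elig_ep & stats::runif(n_ep) < slg$p_ri_manifest
  fhr_route <- strain & !ri_route
  brady <- fhr_route & stats::runif(n_ep) < slg$p_brady
  kind <- ifelse(brady, "brady", ifelse(fhr_route, "tachy", "none"))
  manifest <- ifelse(ri_route, "RI", ifelse(brady, "FHR-brady",
                     ifelse(fhr_route, "FHR-tachy", NA_character_)))

  # working FHR levels (linear structural model), pushed to the excursion
  # level when strain manifests through the FHR
  level <- fhr_base[vi] + fp$work_shift +
    fp$stress_slope * (episodes$utci - fp$stress_ref) +
    fp$psi_effect * (episodes$psi - fp$psi_ref) +
    stats::rnorm(n_ep, 0, fp$noise_sd)
  # excursions are additive on the structural level (a strained fetus keeps
  # its stress/strain-dependent baseline shift), with a guaranteed bound so
  # the classifier's threshold rule always fires
  level[kind == "tachy"] <- pmax(level[kind == "tachy"] + fp$tachy_excursion,
                                 fp$tachy_level)
  level[kind == "brady"] <- pmin(level[kind == "brady"] - fp$brady_excursion,
                                 fp$brady_level)

  # FHR series: baseline timepoint plus the working timepoints
  base_series <- .make_fhr_series(fhr_base, rep("none", nv), fp$series_sd)
  work_series <- .make_fhr_series(level, kind, fp$series_sd)
  ns <- length(.fhr_times)
  fhr_series <- tibble::tibble(
    visit = c(rep(visits$visit, each = ns), rep(episodes$visit, each = ns)),
    timepoint = c(rep("baseline", nv * ns),
                  rep(episodes$timepoint, each = ns)),
    time_min = c(rep(.fhr_times, nv), rep(.fhr_times, n_ep)),
    fhr_bpm = c(base_series, work_series))

  # working-period RI honouring the latent route
  upper_e <- upper_v[vi]
  ri_b_e <- ri_base[vi]
  cat_num <- function(ri, up) 1L + (ri >= up) + (ri >= up + 0.1) + (ri >= 1)
  ri_work <- ri_b_e + stats::rnorm(n_ep, 0, rp$work_jitter_sd)
  ri_work <- .ri_away_from_thresholds(ri_work, upper_e)
  bumped <- !is.na(ri_work) &
    cat_num(ri_work, upper_e) > cat_num(ri_b_e, upper_e) & !ri_route
  ri_work[bumped] <- ri_b_e[bumped]
  if (any(ri_route)) {
    bcat <- cat_num(ri_b_e[ri_route], upper_e[ri_route])
    tgt <- ifelse(bcat == 1, upper_e[ri_route],
           ifelse(bcat == 2, upper_e[ri_route] + 0.1, 1)) +
      0.01 + abs(stats::rnorm(sum(ri_route), 0, rp$raised_sd))
    ri_work[ri_route] <- pmin(tgt, 1)
  }
  ri_work[!elig_ep] <- NA_real_

  # duplicate Doppler readings (symmetric jitter; capped so a single
  # quality-failing duplicate cannot move the mean across a threshold)
  dup <- function(ri_true) {
    n <- length(ri_true)
    d <- pmin(abs(stats::rnorm(n, 0, 0.002)), 0.005)
    q2 <- stats::runif(n) > 0.1
    list(r1 = ri_true - d, r2 = pmin(ri_true + d, 1), q1 = rep(TRUE, n),
         q2 = q2)
  }
  sys_b <- .rtrunc_norm(nv, 45, 5, 30, 60)
  sys_w <- .rtrunc_norm(n_ep, 45, 5, 30, 60)
  d_b <- dup(ri_base); d_w <- dup(ri_work)

  mk_fetal <- function(visit, timepoint, fhr_vals, sys, d) {
    tibble::tibble(
      visit = visit, timepoint = timepoint, fhr_mean = fhr_vals,
      ua_systolic_1 = sys, ua_diastolic_1 = sys * (1 - d$r1),
      quality_1 = d$q1,
      ua_systolic_2 = sys, ua_diastolic_2 = sys * (1 - d$r2),
      quality_2 = d$q2)
  }
  base_mean <- colMeans(matrix(base_series, nrow = ns))
  work_mean <- colMeans(matrix(work_series, nrow = ns))
  fetal <- dplyr::bind_rows(
    mk_fetal(visits$visit, "baseline", base_mean, sys_b, d_b),
    mk_fetal(episodes$visit, episodes$timepoint, work_mean, sys_w, d_w))

  truth <- tibble::tibble(
    visit = episodes$visit, timepoint = episodes$timepoint,
    p_strain = p, strain = strain, manifest = manifest,
    utci = episodes$utci, psi = episodes$psi)
  list(fetal = fetal, fhr_series = fhr_series, truth = truth)
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates the full generative chain for a seeded cohort: participants
#' and covariates, one or two visits each, shift meteorology, maternal
#' physiology and PSI, per-timepoint exposure summaries, and fetal
#' observations tied to the latent strain model. Deterministic for a fixed
#' configuration (the seed lives in the configuration).
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: a list with `participants`,
#'   `visits`, `baselines`, `shift_series`, `fetal`, `fhr_series`,
#'   `episodes` (per-timepoint exposure/strain covariates) and `truth`
#'   (latent strain ground truth), plus the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(config$seed))
  cp <- config$covariate_params
  np <- as.integer(config$n_participants)

  participants <- tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(np)),
    age_years = round(stats::rlnorm(np, cp$age_meanlog, cp$age_sdlog), 1),
    fat_mass_pct = round(.rtrunc_norm(np, cp$fat_mass_mean, cp$fat_mass_sd,
                                      cp$fat_mass_min, cp$fat_mass_max), 1),
    walk_m = round(.rtrunc_norm(np, cp$walk_mean, cp$walk_sd,
                                cp$walk_min, cp$walk_max)))
  b_strain <- stats::rnorm(np, 0, config$strain_logit$re_sd)
  b_hr <- stats::rnorm(np, 0, config$strain_link$hr_participant_sd)
  b_skin <- stats::rnorm(np, 0, config$strain_link$tskin_participant_sd)

  second <- stats::runif(np) < config$second_visit_fraction
  ga1 <- .rtrunc_norm(np, cp$ga_mean, cp$ga_sd, cp$ga_min, cp$ga_max)
  pid <- c(seq_len(np), which(second))
  vnum <- c(rep(1L, np), rep(2L, sum(second)))
  ga <- c(ga1, pmin(ga1[second] + cp$second_visit_gap_weeks, 40))
  nv <- length(pid)
  season <- ifelse(stats::runif(nv) < config$meteo_params$season_mix,
                   "dry", "rainy")
  ord <- order(pid, vnum)
  visits <- tibble::tibble(
    visit = seq_len(nv),
    visit_id = sprintf("V%05d", seq_len(nv)),
    participant_id = participants$participant_id[pid[ord]],
    visit_number = vnum[ord],
    season = season[ord],
    ga_weeks = round(ga[ord], 1),
    any_symptom = stats::runif(nv) < config$symptom_prob,
    b_strain = b_strain[pid[ord]])
  date0 <- as.Date(ifelse(visits$season == "rainy", "2019-08-26",
                          "2019-11-01"))
  span <- ifelse(visits$season == "rainy", 66, 147)
  visits$date <- date0 + floor(stats::runif(nv) * span)

  meteo <- generate_meteorology(config, visits$season, nv)
  phys <- generate_physiology(config, meteo,
                              b_hr = b_hr[pid[ord]],
                              b_skin = b_skin[pid[ord]])

  # per-timepoint exposure and strain covariates (mean or peak up to the
  # observation timepoint)
  H <- config$shift_hours
  reduce_to <- function(x, t, cut) {
    f <- if (config$exposure_basis == "peak") max else mean
    f(x[t <= cut])
  }
  wbgt_s <- wbgt_outdoor(meteo$tnwb_c, meteo$tg_c, meteo$ta_c)
  ep_list <- lapply(c(mid = H / 2, end = H), function(cut) {
    keep <- meteo$t_hours <= cut
    u <- tapply(phys$series$utci_c[keep], meteo$visit[keep],
                if (config$exposure_basis == "peak") max else mean)
    w <- tapply(wbgt_s[keep], meteo$visit[keep],
                if (config$exposure_basis == "peak") max else mean)
    p <- tapply(phys$series$psi[keep], meteo$visit[keep],
                if (config$exposure_basis == "peak") max else mean)
    tibble::tibble(visit = as.integer(names(u)), utci = as.numeric(u),
                   wbgt = as.numeric(w), psi = as.numeric(p))
  })
  episodes <- dplyr::bind_rows(ep_list, .id = "timepoint")
  episodes <- episodes[order(episodes$visit, episodes$timepoint), ]
  episodes$ga_weeks <- visits$ga_weeks[episodes$visit]

  fet <- generate_fetal(config, visits, episodes)

  spm <- config$samples_per_hour
  start <- as.POSIXct(paste(visits$date, "08:00:00"), tz = "UTC")
  shift_series <- tibble::tibble(
    visit_id = visits$visit_id[meteo$visit],
    timestamp = format(start[meteo$visit] + meteo$t_hours * 3600,
                       "%Y-%m-%dT%H:%M:%SZ"),
    ta_c = meteo$ta_c, rh_pct = meteo$rh_pct, tg_c = meteo$tg_c,
    tnwb_c = meteo$tnwb_c, wind_ms = meteo$wind_ms,
    hr_bpm = phys$series$hr_bpm, tskin_c = phys$series$tskin_c,
    utci_c = phys$series$utci_c, psi = phys$series$psi,
    t_hours = meteo$t_hours)

  structure(list(
    config = config,
    participants = participants,
    visits = visits,
    baselines = tibble::tibble(visit_id = visits$visit_id,
                               tymp_c = phys$baselines$tymp_c,
                               hr0_bpm = phys$baselines$hr0_bpm),
    shift_series = shift_series,
    episodes = episodes,
    fetal = fet$fetal, fhr_series = fet$fhr_series, truth = fet$truth
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic heat-stress cohort\n")
  cat(sprintf("  %d participants, %d visits (%d second visits), seed %d\n",
              nrow(x$participants), nrow(x$visits),
              sum(x$visits$visit_number == 2L),
              as.integer(x$config$seed)))
  cat(sprintf("  %d shift samples, %d working episodes (latent strain %.1f%%)\n",
              nrow(x$shift_series), nrow(x$truth),
              100 * mean(x$truth$strain)))
  invisible(x)
}
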