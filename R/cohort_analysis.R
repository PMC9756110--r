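# Vectorised duplicate-Doppler combination following the same rule as
# ri_from_duplicates(): mean over quality-passing readings, NA when both
# fail (equivalence is covered by a test).
.combine_duplicates <- function(ri1, ri2, q1, q2) {
  ifelse(q1 & q2, (ri1 + ri2) / 2,
  ifelse(q1, ri1,
  ifelse(q2, ri2, NA_real_)))
}

#' Classify fetal strain for every working episode of a fetal dataset
#'
#' Applies the composite classifier ([fetal_strain()]) to each working
#' timepoint: duplicate Doppler readings are converted to resistance indices
#' and combined over quality-passing traces, the baseline RI category is
#' compared with the working-period category, and the FHR series is scanned
#' for sustained threshold crossings.
#'
#' @param fetal Per-timepoint fetal table with duplicate Doppler columns
#'   (`ua_systolic_1`, `ua_diastolic_1`, `quality_1`, and `_2` variants) as
#'   produced by the generator or read from `fetal.csv`.
#' @param fhr_series Long FHR table (`visit`, `timepoint`, `time_min`,
#'   `fhr_bpm`).
#' @param visits Visit table with `visit`, `ga_weeks`.
#' @param ri_table RI category thresholds.
#' @param ri_eligible_weeks Doppler eligibility gate (weeks).
#' @return Tibble with one row per working episode: `visit`, `timepoint`,
#'   `fhr_strain`, `ri_strain`, `fetal_strain`, `trigger`.
#' @export
classify_episodes <- function(fetal, fhr_series, visits,
                              ri_table = default_ri_table(),
                              ri_eligible_weeks = 28) {
  safe_ri <- function(s, d) {
    out <- rep(NA_real_, length(s))
    ok <- is.finite(s) & is.finite(d)
    if (any(ok)) out[ok] <- resistance_index(s[ok], d[ok])
    out
  }
  ri_all <- .combine_duplicates(
    safe_ri(fetal$ua_systolic_1, fetal$ua_diastolic_1),
    safe_ri(fetal$ua_systolic_2, fetal$ua_diastolic_2),
    fetal$quality_1, fetal$quality_2)
  base_rows <- fetal$timepoint == "baseline"
  ri_baseline <- stats::setNames(ri_all[base_rows], fetal$visit[base_rows])
  work <- fetal[!base_rows, c("visit", "timepoint")]
  work$ri_now <- ri_all[!base_rows]
  work$ri_baseline <- unname(ri_baseline[as.character(work$visit)])
  work$ga_weeks <- visits$ga_weeks[match(work$visit, visits$visit)]

  # RI arm, vectorised (same rule as fetal_strain(): category increase from
  # baseline, Doppler-eligible visits only)
  ri_used <- is.finite(work$ri_now) & work$ga_weeks >= ri_eligible_weeks
  ri_pos <- rep(FALSE, nrow(work))
  if (any(ri_used)) {
    ri_pos[ri_used] <-
      ri_category(work$ri_now[ri_used], work$ga_weeks[ri_used], ri_table) >
      ri_category(work$ri_baseline[ri_used], work$ga_weeks[ri_used],
                  ri_table)
  }

  # FHR arm, per episode (sustained-window scan)
  key_s <- paste(fhr_series$visit, fhr_series$timepoint)
  split_idx <- split(seq_len(nrow(fhr_series)), key_s)
  keys <- paste(work$visit, work$timepoint)
  fhr_pos <- vapply(keys, function(k) {
    ix <- split_idx[[k]]
    as.logical(fhr_strain(fhr_series$fhr_bpm[ix],
                          fhr_series$time_min[ix]))
  }, logical(1), USE.NAMES = FALSE)

  tibble::tibble(
    visit = work$visit, timepoint = work$timepoint,
    fhr_strain = fhr_pos, ri_strain = ri_pos,
    fetal_strain = fhr_pos | ri_pos,
    trigger = ifelse(fhr_pos & ri_pos, "FHR+RI",
              ifelse(fhr_pos, "FHR", ifelse(ri_pos, "RI", NA_character_))))
}

#' Analysis panel from a synthetic cohort
#'
#' Runs the fetal-strain classifier over the cohort's working episodes and
#' assembles the repeated-measures panel ([build_panel()]) with
#' episode-level heat stress (mean exposure up to the timepoint), maternal
#' PSI, outcomes and covariates.
#'
#' @param cohort A [generate_cohort()] result.
#' @return Panel tibble; see [build_panel()].
#' @export
cohort_panel <- function(cohort) {
  cls <- classify_episodes(
    cohort$fetal, cohort$fhr_series, cohort$visits,
    ri_eligible_weeks = cohort$config$ri_eligible_weeks)
  work <- cohort$fetal[cohort$fetal$timepoint != "baseline", ]
  outcomes <- tibble::tibble(
    visit_id = cohort$visits$visit_id[work$visit],
    timepoint = work$timepoint, fhr = work$fhr_mean)
  outcomes$strain <- cls$fetal_strain[
    match(paste(work$visit, work$timepoint),
          paste(cls$visit, cls$timepoint))]
  exposure <- tibble::tibble(
    visit_id = cohort$visits$visit_id[cohort$episodes$visit],
    timepoint = cohort$episodes$timepoint,
    utci = cohort$episodes$utci, wbgt = cohort$episodes$wbgt)
  strain <- tibble::tibble(
    visit_id = cohort$visits$visit_id[cohort$episodes$visit],
    timepoint = cohort$episodes$timepoint,
    psi = cohort$episodes$psi)
  covariates <- tibble::tibble(
    visit_id = cohort$visits$visit_id,
    participant_id = cohort$visits$participant_id,
    ga_weeks = cohort$visits$ga_weeks)
  covariates <- dplyr::left_join(
    covariates,
    cohort$participants[c("participant_id", "fat_mass_pct", "walk_m")],
    by = "participant_id")
  build_panel(exposure, strain, outcomes, covariates)
}

#' Headline summary statistics of a synthetic cohort
#'
#' The calibration-facing summaries: pooled means (and SDs) of the shift
#' meteorology and exposure indices, maternal peak PSI, baseline and
#' working-period fetal heart rate, and the episode-level fetal-strain
#' fraction as classified by the composite rule.
#'
#' @param cohort A [generate_cohort()] result.
#' @param classified Reuse an existing [classify_episodes()] result
#'   (optional).
#' @return Named list of summary statistics.
#' @export
cohort_summary <- function(cohort, classified = NULL) {
  ss <- cohort$shift_series
  wbgt_s <- wbgt_outdoor(ss$tnwb_c, ss$tg_c, ss$ta_c)
  per_visit <- function(x) tapply(x, ss$visit_id, mean)
  peak_psi <- tapply(ss$psi, ss$visit_id, max)
  if (is.null(classified)) {
    classified <- classify_episodes(
      cohort$fetal, cohort$fhr_series, cohort$visits,
      ri_eligible_weeks = cohort$config$ri_eligible_weeks)
  }
  work <- cohort$fetal$timepoint != "baseline"
  list(
    n_visits = nrow(cohort$visits),
    ta_mean = mean(ss$ta_c), ta_sd = stats::sd(ss$ta_c),
    rh_mean = mean(ss$rh_pct), rh_sd = stats::sd(ss$rh_pct),
    wbgt_mean = mean(per_visit(wbgt_s)),
    utci_mean = mean(per_visit(ss$utci_c)),
    peak_psi_mean = mean(peak_psi), peak_psi_sd = stats::sd(peak_psi),
    fhr_baseline_mean = mean(cohort$fetal$fhr_mean[!work]),
    fhr_working_mean = mean(cohort$fetal$fhr_mean[work]),
    fhr_working_sd = stats::sd(cohort$fetal$fhr_mean[work]),
    strain_fraction = mean(classified$fetal_strain)
  )
}

#' Implied total effect of heat stress in a generated cohort
#'
#' The generator specifies the direct heat-stress effect and the PSI effect;
#' the total effect (model 1) additionally carries the mediated path through
#' maternal strain and has no simple closed form on the odds-ratio scale.
#' This helper estimates it by simulating a large cohort and fitting the
#' total-effect model.
#'
#' @param config A [cohort_config()] (its seed is used).
#' @param n_participants Cohort size for the simulation (default 2000).
#' @param outcome `"A"` or `"B"`.
#' @return One-row coefficient tibble for the heat-stress term of model 1.
#' @export
implied_total_effect <- function(config = cohort_config(),
                                 n_participants = 2000,
                                 outcome = c("B", "A")) {
  outcome <- match.arg(outcome)
  config$n_participants <- n_participants
  cfg <- validate_cohort_config(unclass(config))
  panel <- cohort_panel(generate_cohort(cfg))
  ft <- fit_model(panel, outcome = outcome, model_id = 1,
                  stress_index = "utci")
  ft$terms[ft$terms$term == "heat_stress", ]
}
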