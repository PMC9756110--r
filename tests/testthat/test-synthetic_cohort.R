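test_that("configuration validation names the offending field", {
  expect_error(cohort_config(second_visit_fraction = 1.4),
               "second_visit_fraction")
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(meteo_params = list(ta_within_sd = -1)),
               "SD")
  expect_error(cohort_config(not_a_field = 1), "unknown configuration")
  expect_error(cohort_config(meteo_params = list(bogus = 1)),
               "unknown configuration")
  expect_s3_class(cohort_config(), "cohort_config")
})

test_that("identical seed and configuration give identical cohorts", {
  cfg <- cohort_config(seed = 123, n_participants = 25)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (el in c("participants", "visits", "baselines", "shift_series",
               "fetal", "fhr_series", "episodes", "truth")) {
    expect_identical(a[[el]], b[[el]])
  }
  c2 <- generate_cohort(cohort_config(seed = 124, n_participants = 25))
  expect_false(identical(a$shift_series, c2$shift_series))
})

test_that("cohort structure matches the configured sampling design", {
  cfg <- cohort_config(seed = 2, n_participants = 92)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$participants), 92)
  nv <- nrow(ch$visits)
  expect_gte(nv, 92)
  expect_true(abs(nv - 92 * 1.33) < 92 * 0.33)  # binomial spread
  expect_true(all(table(ch$visits$participant_id) %in% 1:2))
  # every working episode has complete covariates in the panel
  p <- cohort_panel(ch)
  expect_equal(nrow(p), nrow(ch$truth))
  expect_true(all(stats::complete.cases(p)))
  # minimal configuration runs
  tiny <- generate_cohort(cohort_config(seed = 7, n_participants = 1,
                                        second_visit_fraction = 0,
                                        shift_hours = 1))
  expect_equal(nrow(tiny$visits), 1)
  expect_equal(nrow(tiny$shift_series), tiny$config$samples_per_hour)
})

test_that("generated series respect physical bounds", {
  ch <- generate_cohort(cohort_config(seed = 9, n_participants = 120))
  ss <- ch$shift_series
  expect_true(all(ss$hr_bpm >= 40 & ss$hr_bpm <= 220))
  expect_true(all(ss$ta_c > 15 & ss$ta_c < 50))
  expect_true(all(ss$tskin_c > 25 & ss$tskin_c < 45))
  expect_true(all(ss$rh_pct >= 0 & ss$rh_pct <= 100))
  expect_true(all(ss$wind_ms >= 0))
  expect_true(all(ss$tg_c >= ss$ta_c - 5))
  expect_true(all(ch$fhr_series$fhr_bpm >= 50 &
                    ch$fhr_series$fhr_bpm <= 250))
})

test_that("noise-free meteorology is the deterministic diurnal skeleton", {
  cfg <- cohort_config(seed = 1, meteo_params = list(
    ta_between_sd = 0, ta_within_sd = 0, ta_diurnal_amp = 0,
    rh_between_sd = 0, rh_within_sd = 0, wind_sdlog = 0,
    solar_sd = 0, solar_within_sd = 0))
  m <- generate_meteorology(cfg, season = "dry", n_visits = 3)
  expect_equal(length(unique(round(m$ta_c, 10))), 1)
  expect_equal(unique(m$ta_c), unname(cfg$meteo_params$ta_mean["dry"]))
  expect_equal(length(unique(round(m$rh_pct, 10))), 1)
  expect_error(generate_meteorology(cfg, season = "monsoon"), "season")
})

test_that("zero strain-link slopes give near-zero PSI response to heat", {
  cfg <- cohort_config(seed = 4, n_participants = 60,
                       strain_link = list(tskin_slope = 0, hr_slope = 0))
  ch <- generate_cohort(cfg)
  # PSI no longer tracks UTCI
  r <- cor(ch$episodes$utci, ch$episodes$psi)
  expect_lt(abs(r), 0.2)
})

test_that("hotter climates produce stochastically larger peak strain", {
  base <- generate_cohort(cohort_config(seed = 6, n_participants = 150))
  hot <- generate_cohort(cohort_config(
    seed = 6, n_participants = 150,
    meteo_params = list(ta_mean = c(rainy = 36.5, dry = 40.5))))
  peak <- function(ch) mean(tapply(ch$shift_series$psi,
                                   ch$shift_series$visit_id, max))
  expect_gt(peak(hot), peak(base) + 0.5)
})

test_that("strain incidence increases strictly along a direct-effect grid", {
  inc <- vapply(c(0, 0.08, 0.16, 0.30), function(lor) {
    ch <- generate_cohort(cohort_config(
      seed = 15, n_participants = 900,
      strain_logit = list(stress_lor = lor)))
    mean(ch$truth$strain)
  }, numeric(1))
  expect_true(all(diff(inc) > 0))
})

test_that("the composite classifier recovers the latent strain events exactly", {
  ch <- generate_cohort(cohort_config(seed = 8, n_participants = 200))
  cls <- classify_episodes(ch$fetal, ch$fhr_series, ch$visits)
  m <- match(paste(ch$truth$visit, ch$truth$timepoint),
             paste(cls$visit, cls$timepoint))
  expect_equal(cls$fetal_strain[m], ch$truth$strain)
  # manifestation routes agree with the firing trigger
  ri_cases <- which(ch$truth$manifest == "RI")
  expect_true(all(cls$ri_strain[m][ri_cases]))
})

test_that("vectorised duplicate combination matches the scalar rule", {
  set.seed(44)
  for (i in 1:20) {
    ri <- runif(2, 0.4, 0.9)
    q <- runif(2) > 0.3
    if (!any(q)) next
    expect_equal(
      heatstrain:::.combine_duplicates(ri[1], ri[2], q[1], q[2]),
      ri_from_duplicates(ri, q))
  }
})

test_that("fetal generation demands complete exposure", {
  cfg <- cohort_config(seed = 3, n_participants = 5)
  ch <- generate_cohort(cfg)
  eps <- ch$episodes
  eps$utci[2] <- NA
  visits <- ch$visits
  expect_error(generate_fetal(cfg, visits, eps), "missing exposure")
})
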