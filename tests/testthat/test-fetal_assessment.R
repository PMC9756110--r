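test_that("resistance index is the normalised systolic-diastolic differential", {
  expect_equal(resistance_index(60, 15), 0.75)
  expect_equal(resistance_index(50, 50), 0)
  expect_equal(resistance_index(40, 0), 1)
  expect_error(resistance_index(0, 0), "systolic")
  expect_error(resistance_index(40, 45), "diastolic")
  # bounded and monotone decreasing in diastolic velocity
  d <- seq(0, 50, 5)
  ri <- resistance_index(50, d)
  expect_true(all(ri >= 0 & ri <= 1))
  expect_true(all(diff(ri) < 0))
})

test_that("duplicate RI readings combine by quality-filtered mean", {
  expect_equal(ri_from_duplicates(c(0.70, 0.72), c(TRUE, TRUE)), 0.71)
  expect_equal(ri_from_duplicates(c(0.70, 0.95), c(TRUE, FALSE)), 0.70)
  expect_error(ri_from_duplicates(c(0.7, 0.8), c(FALSE, FALSE)),
               "quality")
})

test_that("RI risk categories follow the gestational-age threshold table", {
  expect_equal(as.character(ri_category(1.0, 30)),
               "absent end-diastolic flow")
  expect_equal(as.character(ri_category(0.55, 34)), "normal")
  up <- default_ri_table()
  u34 <- approx(up$ga_week, up$upper_normal_ri, 34)$y
  expect_equal(as.character(ri_category(u34 + 0.001, 34)), "raised")
  expect_equal(as.character(ri_category(u34 + 0.101, 34)),
               "severely raised")
  expect_error(ri_category(0.6, 10), "threshold table")
  expect_error(ri_category(1.2, 30), "RI must lie")
  # ordinal monotone in RI
  x <- seq(0, 1, 0.01)
  expect_true(all(diff(as.integer(ri_category(x, 32))) >= 0))
})

test_that("sustained FHR rule fires on 5-minute threshold crossings", {
  t10 <- seq(0, 6, 0.5)
  expect_true(as.logical(fhr_strain(rep(165, length(t10)), t10)))
  expect_false(as.logical(fhr_strain(rep(150, 121), seq(0, 60, 0.5))))
  # 110 bpm for 3 min then recovery: not sustained
  tr <- c(rep(110, 7), rep(130, 6))
  expect_false(as.logical(fhr_strain(tr, seq(0, 6, 0.5))))
  # bradycardia sustained for exactly 5 minutes is positive (inclusive)
  br <- c(rep(112, 11), rep(130, 2))
  expect_true(as.logical(fhr_strain(br, seq(0, 6, 0.5))))
  expect_equal(attr(fhr_strain(br, seq(0, 6, 0.5)), "trigger"),
               "bradycardia")
  # a 160 bpm sample counts (inclusive threshold)
  expect_true(as.logical(fhr_strain(rep(160, 11), seq(0, 5, 0.5))))
})

test_that("short series are indeterminate rather than negative", {
  short <- fhr_strain(rep(150, 5), seq(0, 2, 0.5))
  expect_false(as.logical(short))
  expect_true(attr(short, "indeterminate"))
  long_neg <- fhr_strain(rep(150, 13), seq(0, 6, 0.5))
  expect_false(attr(long_neg, "indeterminate"))
  expect_error(fhr_strain(numeric(0), numeric(0)), "empty")
})

test_that("instantaneous tachycardia switch relaxes the sustained rule", {
  spike <- c(rep(150, 6), 161, rep(150, 6))
  tm <- seq(0, 6, 0.5)
  expect_false(as.logical(fhr_strain(spike, tm)))
  expect_true(as.logical(fhr_strain(spike, tm, instant_tachy = TRUE)))
})

test_that("raising a tachycardic series keeps it strain-positive", {
  set.seed(21)
  tm <- seq(0, 6.5, 0.5)
  for (i in 1:20) {
    base <- 162 + abs(rnorm(length(tm), 2, 2))
    stopifnot(as.logical(fhr_strain(base, tm)))
    expect_true(as.logical(fhr_strain(base + runif(1, 0, 30), tm)))
  }
})

test_that("fetal strain is the disjunction of its components", {
  tm <- seq(0, 6, 0.5)
  # RI category increase with normal FHR
  r <- fetal_strain(rep(140, 13), tm, ri_now = 0.80, ri_baseline = 0.60,
                    ga_weeks = 32)
  expect_true(r$fetal_strain)
  expect_equal(r$trigger, "RI")
  # FHR-only pathway when Doppler unavailable
  r2 <- fetal_strain(rep(165, 13), tm, ri_now = NA, ri_baseline = NA,
                     ga_weeks = 25)
  expect_true(r2$fetal_strain)
  expect_equal(r2$trigger, "FHR")
  # all normal
  r3 <- fetal_strain(rep(140, 13), tm, 0.61, 0.60, 34)
  expect_false(r3$fetal_strain)
  expect_error(fetal_strain(rep(140, 13), tm, ri_now = 0.7,
                            ri_baseline = NA, ga_weeks = 32), "baseline RI")
  # under 28 weeks the RI is ignored even if supplied
  r4 <- fetal_strain(rep(140, 13), tm, 0.95, 0.60, ga_weeks = 26)
  expect_false(r4$fetal_strain)
})

test_that("fetal strain equals the OR of components on randomised inputs", {
  set.seed(33)
  tm <- seq(0, 6.5, 0.5)
  for (i in 1:40) {
    lev <- runif(1, 100, 180)
    fhr <- pmax(pmin(lev + rnorm(length(tm), 0, 3), 240), 60)
    ga <- runif(1, 28, 40)
    rib <- runif(1, 0.4, 0.9)
    rin <- pmin(pmax(rib + rnorm(1, 0, 0.15), 0), 1)
    r <- fetal_strain(fhr, tm, rin, rib, ga)
    expect_identical(r$fetal_strain, r$fhr_strain || r$ri_strain)
  }
})
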