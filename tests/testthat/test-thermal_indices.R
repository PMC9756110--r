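test_that("outdoor WBGT is the standard weighted composition", {
  expect_equal(wbgt_outdoor(25, 35, 30), 27.5)
  expect_equal(wbgt_outdoor(20, 40, 30), 25.0)
  expect_equal(wbgt_outdoor(31.2, 31.2, 31.2), 31.2)
})

test_that("WBGT stays inside the convex hull of its inputs", {
  set.seed(42)
  tnwb <- runif(200, 15, 32)
  tg <- runif(200, 25, 60)
  ta <- runif(200, 20, 46)
  w <- wbgt_outdoor(tnwb, tg, ta)
  expect_true(all(w >= pmin(tnwb, tg, ta) - 1e-12))
  expect_true(all(w <= pmax(tnwb, tg, ta) + 1e-12))
})

test_that("mean radiant temperature reduces to air temperature without a radiant load", {
  expect_equal(mean_radiant_temperature(30, 30, 0), 30)
  expect_equal(mean_radiant_temperature(25, 25, 3.7), 25)
})

test_that("mean radiant temperature follows the forced-convection globe formula", {
  # direct evaluation of the standard formula, coded separately
  tg <- 40; ta <- 30; v <- 1.0; d <- 0.15; eps <- 0.95
  expected <- ((tg + 273.15)^4 +
                 1.1e8 * v^0.6 / (eps * d^0.4) * (tg - ta))^0.25 - 273.15
  expect_equal(mean_radiant_temperature(tg, ta, v, d, eps), expected,
               tolerance = 1e-10)
  # strictly increasing in the globe reading
  tmrts <- mean_radiant_temperature(seq(31, 55, 2), 30, 1.0)
  expect_true(all(diff(tmrts) > 0))
  expect_error(mean_radiant_temperature(40, 30, 1, globe_diameter = 0),
               "globe_diameter")
})

test_that("Magnus saturation vapour pressure agrees with the Hardy reference", {
  ta <- seq(0, 45, by = 0.5)
  diff_kpa <- abs(saturation_vapour_pressure(ta) / 10 -
                    hardy_svp_pa(ta) / 1000)
  expect_lt(max(diff_kpa), 0.05)
})

test_that("UTCI matches the independently coded reference polynomial", {
  set.seed(7)
  n <- 300
  ta <- runif(n, -45, 48)
  va <- runif(n, 0.5, 17)
  dt <- runif(n, -28, 68)
  pa <- runif(n, 0, 4.5)
  ref <- ta + utci_reference_offset(ta, va, dt, pa)
  got <- ta + heatstrain:::.utci_offset(ta, va, dt, pa)
  expect_lt(max(abs(got - ref)), 0.1)
})

test_that("UTCI behaves physically in the warm envelope", {
  # near-neutral conditions give an equivalent temperature near Ta
  expect_equal(utci(25, 25, 1, 50), 24.6, tolerance = 0.05)
  expect_equal(utci(30, 30, 1, 50), 30.3, tolerance = 0.05)
  # radiant load raises UTCI monotonically
  u <- utci(rep(35, 9), seq(35, 75, 5), 1, 40)
  expect_true(all(diff(u) > 0))
  # more humidity feels hotter in humid heat
  expect_gt(utci(34, 40, 1, 70), utci(34, 40, 1, 30))
})

test_that("out-of-envelope UTCI inputs are clamped with a warning", {
  expect_warning(u1 <- utci(30, 30, 0.1, 50), "envelope")
  expect_equal(u1, utci(30, 30, 0.5, 50))
  expect_error(utci(NA, 30, 1, 50), "non-finite")
  expect_error(utci(30, 30, 1, 150), "rh")
})

test_that("WBGT categories and the occupational flag follow the band edges", {
  expect_equal(as.integer(wbgt_category(20.0)), 1L)
  expect_false(attr(wbgt_category(20.0), "heat_stress"))
  expect_true(attr(wbgt_category(24.9), "heat_stress"))
  expect_false(heat_stress_flag(24.8))
  expect_equal(as.integer(wbgt_category(42.0)), 5L)
  # monotone step function
  x <- seq(15, 45, by = 0.1)
  expect_true(all(diff(as.integer(wbgt_category(x))) >= 0))
})

test_that("UTCI assessment categories follow the ten-class scale", {
  expect_equal(as.character(utci_category(51.3)), "extreme heat stress")
  expect_equal(as.character(utci_category(34.0)), "strong heat stress")
  expect_equal(as.character(utci_category(9.0)), "no thermal stress")
  expect_equal(as.character(utci_category(46.0)), "very strong heat stress")
  expect_equal(as.character(utci_category(46.1)), "extreme heat stress")
  x <- seq(-45, 55, by = 0.5)
  expect_true(all(diff(as.integer(utci_category(x))) >= 0))
})

test_that("exposure summaries reduce means and peaks correctly", {
  one <- tibble::tibble(ta_c = 30, rh_pct = 40, tg_c = 36, tnwb_c = 24,
                        wind_ms = 1)
  s1 <- summarise_exposure(one)
  expect_equal(s1$wbgt_mean, s1$wbgt_peak)
  expect_equal(s1$utci_mean, s1$utci_peak)

  # two samples engineered to WBGT 25 and 29
  two <- tibble::tibble(ta_c = c(25, 29), rh_pct = 40, tg_c = c(25, 29),
                        tnwb_c = c(25, 29), wind_ms = 1)
  s2 <- summarise_exposure(two)
  expect_equal(s2$wbgt_mean, 27)
  expect_equal(s2$wbgt_peak, 29)

  # reordering samples changes neither means nor peaks
  set.seed(1)
  ta <- runif(24, 28, 40)
  ser <- tibble::tibble(ta_c = ta, rh_pct = runif(24, 5, 60),
                        tg_c = ta + runif(24, 0, 12),
                        tnwb_c = runif(24, 18, 27),
                        wind_ms = runif(24, 0.2, 3))
  perm <- ser[sample(24), ]
  expect_equal(suppressWarnings(summarise_exposure(ser)),
               suppressWarnings(summarise_exposure(perm)))

  expect_error(summarise_exposure(ser[0, ]), "empty")
  bad <- ser; bad$rh_pct[1] <- 150
  expect_error(summarise_exposure(bad), "humidity")
})
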