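test_that("tympanic measurement takes the highest available reading", {
  expect_equal(tympanic_measurement(c(36.8, 36.9, 37.1, 36.7)), 37.1)
  expect_equal(tympanic_measurement(rep(36.5, 4)), 36.5)
  expect_equal(tympanic_measurement(c(36.5, NA, 36.9, NA)), 36.9)
  expect_error(tympanic_measurement(c(NA_real_, NA_real_)), "no usable")
})

test_that("the modified PSI reproduces hand-evaluated values", {
  expect_equal(as.numeric(psi_mod(37.0, 37.0, 80, 80)), 0)
  expect_equal(as.numeric(psi_mod(39.5, 37.0, 180, 80)), 10)
  expect_equal(as.numeric(psi_mod(38.0, 37.0, 130, 80)), 4.5,
               tolerance = 1e-12)
})

test_that("PSI preserves and flags out-of-scale values", {
  low <- psi_mod(36.0, 37.0, 70, 80)
  expect_lt(as.numeric(low), 0)           # not clamped
  expect_true(attr(low, "out_of_scale"))
  high <- psi_mod(40.2, 37.0, 170, 60)
  expect_gt(as.numeric(high), 10)
  expect_true(attr(high, "out_of_scale"))
  mid <- psi_mod(38, 37, 120, 80)
  expect_false(attr(mid, "out_of_scale"))
})

test_that("PSI rejects baselines that break the denominators", {
  expect_error(psi_mod(38, 39.5, 120, 80), "tympanic")
  expect_error(psi_mod(38, 40.2, 120, 80), "tympanic")
  expect_error(psi_mod(38, 37, 120, 180), "heart rate")
})

test_that("PSI increases strictly in skin temperature and heart rate", {
  set.seed(11)
  for (i in 1:25) {
    ty <- runif(1, 35.5, 38.5)
    hr0 <- runif(1, 55, 110)
    skin <- sort(runif(5, 30, 39.4))
    hr <- sort(runif(5, 50, 175))
    expect_true(all(diff(as.numeric(psi_mod(skin, ty, 100, hr0))) > 0))
    expect_true(all(diff(as.numeric(psi_mod(36, ty, hr, hr0))) > 0))
  }
})

test_that("PSI series reduce to elementwise scores with mean and peak", {
  rest <- tibble::tibble(tskin_c = rep(36.8, 10), hr_bpm = rep(75, 10))
  s <- psi_series(rest, t_tymp0 = 36.8, hr0 = 75)
  expect_equal(s$psi, rep(0, 10))
  expect_equal(s$peak_psi, 0)

  one_hot <- tibble::tibble(tskin_c = c(rep(36.8, 9), 38.2),
                            hr_bpm = c(rep(75, 9), 150))
  s2 <- psi_series(one_hot, 36.8, 75)
  expect_equal(s2$peak_psi, as.numeric(psi_mod(38.2, 36.8, 150, 75)))
  expect_equal(s2$mean_psi, mean(s2$psi))
  # mean/peak invariant to reordering
  perm <- one_hot[sample(10), ]
  s3 <- psi_series(perm, 36.8, 75)
  expect_equal(s3$peak_psi, s2$peak_psi)
  expect_equal(s3$mean_psi, s2$mean_psi)
  expect_error(psi_series(rest[0, ], 36.8, 75), "empty")
})

test_that("PAEE equation reproduces hand evaluations and floors at zero", {
  v <- paee_method_a(40, 30, 50, 55)
  expect_equal(as.numeric(v), 5 * 40 + 0.23 * 40 * 30 + 2.2 * 30 +
                 9.2 * log(50) - 2.6 * 55 - 82, tolerance = 1e-12)
  expect_equal(as.numeric(v), 352.9906116, tolerance = 1e-6)

  z <- paee_method_a(0, 0, 1, 60)
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "raw"), -238)
  expect_true(attr(z, "floored"))
  expect_error(paee_method_a(10, 10, 0, 60), "rmssd")
})

test_that("PAEE is affine in HRaS with the hand-computed slope", {
  h3 <- 30
  slope <- (as.numeric(paee_method_a(41, h3, 50, 55)) -
              as.numeric(paee_method_a(40, h3, 50, 55)))
  expect_equal(slope, 5 + 0.23 * h3, tolerance = 1e-9)
  hras <- seq(20, 80, 10)
  out <- as.numeric(paee_method_a(hras, h3, 50, 55))
  expect_true(all(diff(out) > 0))
})

test_that("observational METs are time-weighted with strict lookup", {
  lk <- tibble::tibble(task = c("a", "b"), met = c(3, 5))
  expect_equal(mets_method_b(tibble::tibble(task = "a", minutes = 60),
                             tibble::tibble(task = "a", met = 4.2)), 4.2)
  expect_equal(mets_method_b(tibble::tibble(task = c("a", "b"),
                                            minutes = c(30, 30)), lk), 4)
  expect_equal(mets_method_b(tibble::tibble(task = c("a", "b"),
                                            minutes = c(90, 30)), lk), 3.5)
  expect_error(mets_method_b(tibble::tibble(task = "c", minutes = 10), lk),
               "unknown task.*c")
  expect_error(mets_method_b(lk[0, ], lk), "empty")
})

test_that("METs reconciliation prefers in-range wearable estimates", {
  expect_equal(mets_reconcile(20, 4.2), list(mets = 4.2, provenance = "B"))
  expect_equal(mets_reconcile(5.0, 4.0), list(mets = 5.0, provenance = "A"))
  # bounds are inclusive
  expect_equal(mets_reconcile(2.0, 9.0)$mets, 2.0)
  expect_equal(mets_reconcile(15.0, 9.0)$provenance, "A")
  expect_equal(mets_reconcile(1.9, 9.0)$provenance, "B")
  expect_error(mets_reconcile(20, NA), "no method B")
  # provenance is A exactly when method A lies in [2, 15]
  for (a in c(1, 2, 7, 15, 16)) {
    expect_equal(mets_reconcile(a, 5)$provenance,
                 if (a >= 2 && a <= 15) "A" else "B")
  }
})
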