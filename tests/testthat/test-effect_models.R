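make_join_inputs <- function() {
  exposure <- tibble::tibble(
    visit_id = rep(c("V1", "V2"), each = 2),
    timepoint = rep(c("mid", "end"), 2),
    utci = c(33, 34, 36, 37), wbgt = c(26, 27, 29, 30))
  strain <- exposure[c("visit_id", "timepoint")]
  strain$psi <- c(2, 3, 4, 5)
  outcomes <- exposure[c("visit_id", "timepoint")]
  outcomes$fhr <- c(140, 145, 150, 155)
  outcomes$strain <- c(FALSE, FALSE, TRUE, TRUE)
  covariates <- tibble::tibble(
    visit_id = c("V1", "V2"), participant_id = c("P1", "P2"),
    ga_weeks = c(30, 32), fat_mass_pct = c(28, 31), walk_m = c(450, 430))
  list(exposure = exposure, strain = strain, outcomes = outcomes,
       covariates = covariates)
}

test_that("panel assembly joins episodes and keeps only complete rows", {
  j <- make_join_inputs()
  p <- build_panel(j$exposure, j$strain, j$outcomes, j$covariates)
  expect_equal(nrow(p), 4)
  expect_equal(p$heat_strain, c(2, 3, 4, 5))
  expect_equal(attr(p, "audit")$n_dropped_incomplete, 0)

  j$covariates$fat_mass_pct[1] <- NA
  p2 <- build_panel(j$exposure, j$strain, j$outcomes, j$covariates)
  expect_equal(nrow(p2), 2)   # both episodes of the incomplete visit drop
  expect_equal(attr(p2, "audit")$n_dropped_incomplete, 2)
})

test_that("panel assembly rejects duplicate keys and orphan visits", {
  j <- make_join_inputs()
  expect_error(build_panel(rbind(j$exposure, j$exposure[1, ]), j$strain,
                           j$outcomes, j$covariates), "duplicate")
  expect_error(build_panel(j$exposure, j$strain, j$outcomes,
                           j$covariates[1, ]), "orphan|without covariates")
  expect_warning(p0 <- build_panel(j$exposure, j$strain, j$outcomes[0, ],
                                   j$covariates), "empty")
  expect_equal(nrow(p0), 0)
})

test_that("effect models return coherent fits for both outcomes", {
  panel <- make_test_panel()
  for (m in 1:3) {
    fb <- fit_model(panel, "B", m, "utci")
    expect_s3_class(fb, "hs_fit")
    expect_true(all(fb$terms$or > 0))
    expect_true(all(fb$terms$conf_low < fb$terms$estimate &
                      fb$terms$estimate < fb$terms$conf_high))
    expect_equal(nrow(fb$terms), c(2, 3, 6)[m])
  }
  fa <- fit_model(panel, "A", 1, "wbgt")
  expect_false("or" %in% names(fa$terms))
  expect_gt(fa$terms$estimate[fa$terms$term == "heat_stress"], 0)

  one_class <- panel
  one_class$outcome_strain <- FALSE
  expect_error(fit_model(one_class, "B", 1, "utci"), "single class")
  expect_error(fit_model(panel[0, ], "B", 1, "utci"), "empty panel")
})

test_that("mixed-model estimator is available and broadly agrees", {
  panel <- make_test_panel()
  fg <- fit_model(panel, "A", 2, "utci", estimator = "gee")
  fm <- fit_model(panel, "A", 2, "utci", estimator = "glmm")
  eg <- fg$terms$estimate[fg$terms$term == "heat_stress"]
  em <- fm$terms$estimate[fm$terms$term == "heat_stress"]
  expect_lt(abs(eg - em), 0.3)
})

test_that("spline comparison selects shapes that match the generating truth", {
  lin <- make_linear_panel(1)
  sc <- spline_comparison(lin, "A", "utci")
  expect_equal(nrow(sc), 3)
  expect_equal(sum(sc$winner), 1)
  expect_equal(sc$df, c(2, 4, 4))
  expect_equal(sc$shape[sc$winner], "linear")

  hinge <- make_linear_panel(1, threshold = 1.5)
  sc2 <- spline_comparison(hinge, "A", "utci")
  expect_true(sc2$shape[sc2$winner] != "linear")

  degen <- lin
  degen$stress_utci <- 30
  expect_error(spline_comparison(degen, "A", "utci"), "degenerate")
})

test_that("paired shift test follows the signed-rank conventions", {
  expect_warning(r0 <- paired_shift_test(rep(1, 6), rep(1, 6)), "zero")
  expect_equal(r0$p_value, 1)
  expect_equal(r0$n_effective, 0L)

  base <- c(36.4, 36.6, 36.5, 36.8, 36.3, 36.7, 36.5, 36.6, 36.4, 36.9,
            36.5, 36.2, 36.8, 36.6, 36.4, 36.7, 36.5, 36.3, 36.6, 36.5)
  r1 <- paired_shift_test(base, base + 2)
  expect_lt(r1$p_value, 0.001)
  expect_equal(r1$n_effective, 20L)

  eps <- rep(c(0.01, -0.01), 10)
  r2 <- paired_shift_test(base, base + eps)
  expect_gt(r2$p_value, 0.5)
  expect_error(paired_shift_test(1:3, 2:4), "at least 5")
})

test_that("exact versus approximate signed-rank switching is by size and ties", {
  set.seed(8)
  b <- rnorm(10)
  r <- paired_shift_test(b, b + rnorm(10, 0.2))
  expect_match(r$method, "exact")
  b2 <- rnorm(40)
  r2 <- paired_shift_test(b2, b2 + rnorm(40, 0.2))
  expect_match(r2$method, "normal approximation")
})

test_that("index correlation is Pearson's r with guards", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(index_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(index_correlation(x, -x)$r, -1)
  set.seed(5)
  big <- index_correlation(rnorm(5000), rnorm(5000))
  expect_lt(abs(big$r), 0.05)
  expect_error(index_correlation(1:2, 1:2), "3 complete")
  expect_error(index_correlation(rep(1, 5), 1:5), "constant")
})

test_that("two-proportion sample size matches the classical formula", {
  s <- sample_size_two_proportions(0.05, 0.30, 0.05, 0.80)
  expect_equal(s$n_per_group, 36)
  expect_equal(s$n_total, 72)
  expect_gt(s$n_per_group_corrected, s$n_per_group)
  # symmetry in the two proportions
  s2 <- sample_size_two_proportions(0.30, 0.05, 0.05, 0.80)
  expect_equal(s2$n_per_group, s$n_per_group)
  # monotone in power
  ns <- vapply(c(0.5, 0.8, 0.9, 0.99), function(pw)
    sample_size_two_proportions(0.05, 0.30, power = pw)$n_per_group,
    numeric(1))
  expect_true(all(diff(ns) > 0))
  expect_error(sample_size_two_proportions(0.2, 0.2), "differ")
  expect_error(sample_size_two_proportions(0, 0.3), "in \\(0, 1\\)")
})

test_that("model diagnostics report the three assumption checks", {
  panel <- make_test_panel()
  ft <- fit_model(panel, "A", 2, "utci")
  dg <- model_diagnostics(ft, panel)
  expect_named(dg, c("linearity", "levene", "normality", "unreliable"))
  expect_false(dg$unreliable)
  expect_true(is.finite(dg$levene$p_value))
  expect_true(is.finite(dg$normality$p_value))
  tiny <- panel[1:6, ]
  ft2 <- suppressWarnings(fit_model(tiny, "A", 1, "utci"))
  dg2 <- suppressWarnings(model_diagnostics(ft2, tiny))
  expect_true(dg2$unreliable)
})

test_that("variance inflation with exposure is detected by Levene's test", {
  set.seed(12)
  rej <- replicate(20, {
    p <- make_linear_panel(sample.int(1e6, 1))
    p$outcome_fhr <- p$outcome_fhr +
      rnorm(nrow(p), 0, 0.4 * pmax(p$stress_utci - 30, 0))
    ft <- fit_model(p, "A", 1, "utci")
    model_diagnostics(ft, p)$levene$p_value < 0.05
  })
  expect_gt(mean(rej), 0.5)
})
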