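# Deterministic fixtures shared across test files.

# Small clustered dataset with known structure, used to cross-check the
# estimating-equation fitter against independently computed reference values.
make_gee_fixture <- function() {
  set.seed(99)
  n_cluster <- 40
  n_per <- 4
  id <- rep(seq_len(n_cluster), each = n_per)
  x1 <- round(rnorm(n_cluster * n_per), 6)
  x2 <- rep(round(rnorm(n_cluster), 6), each = n_per)
  b <- rep(round(rnorm(n_cluster, 0, 0.7), 6), each = n_per)
  eta <- -0.3 + 0.8 * x1 - 0.5 * x2 + b
  y_bin <- as.integer(round(runif(n_cluster * n_per), 6) < plogis(eta))
  y_gauss <- round(2 + 1.5 * x1 + 0.7 * x2 + b +
                     round(rnorm(n_cluster * n_per), 6), 6)
  data.frame(id = id, x1 = x1, x2 = x2, y_bin = y_bin, y_gauss = y_gauss)
}

# Small complete panel for model-fitting unit tests (fast, deterministic).
make_test_panel <- function(seed = 3, n_participants = 250) {
  cohort_panel(generate_cohort(cohort_config(seed = seed,
                                             n_participants = n_participants)))
}

# Panel whose continuous outcome is exactly linear in the exposure (plus a
# cluster intercept and noise); `threshold` adds a hinge effect above 38 degC
# for spline-detection checks.
make_linear_panel <- function(seed, n_clusters = 250, threshold = 0) {
  set.seed(seed)
  id <- rep(seq_len(n_clusters), each = 4)
  x <- pmax(rnorm(4 * n_clusters, 34, 3.7), 20)
  y <- 2 + 0.4 * x + rep(rnorm(n_clusters), each = 4) +
    rnorm(4 * n_clusters, 0, 1.5)
  if (threshold > 0) y <- y + threshold * pmax(x - 38, 0)
  tibble::tibble(
    participant_id = id, visit_id = id, timepoint = "end",
    outcome_fhr = y, outcome_strain = rep(c(TRUE, FALSE), 2 * n_clusters),
    stress_utci = x, stress_wbgt = x - 7, heat_strain = 1,
    fitness = 1, fat_mass_pct = 1, ga_weeks = 30)
}
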