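#' Assemble the repeated-measures analysis panel
#'
#' Joins per-episode exposure, maternal strain, fetal outcomes and
#' participant covariates into one row per visit-timepoint, keeping only
#' complete rows (multivariable analyses run on complete data). The join
#' audit (rows dropped and why) is attached as attribute `"audit"`.
#'
#' @param exposure Tibble with `visit_id`, `timepoint`, `utci`, `wbgt`
#'   (episode-level heat stress: mean exposure up to the observation
#'   timepoint).
#' @param strain Tibble with `visit_id`, `timepoint`, `psi` (mean maternal
#'   PSI up to the timepoint).
#' @param outcomes Tibble with `visit_id`, `timepoint`, `fhr`,
#'   `strain` (logical fetal-strain outcome).
#' @param covariates Tibble with `visit_id`, `participant_id`, `ga_weeks`,
#'   `fat_mass_pct`, `walk_m`.
#' @return Tibble with columns `participant_id`, `visit_id`, `timepoint`,
#'   `outcome_fhr`, `outcome_strain`, `stress_utci`, `stress_wbgt`,
#'   `heat_strain`, `fitness`, `fat_mass_pct`, `ga_weeks`.
#' @export
build_panel <- function(exposure, strain, outcomes, covariates) {
  key_dup <- function(df, keys, what) {
    if (anyDuplicated(df[keys])) {
      stop("duplicate keys in ", what, " table", call. = FALSE)
    }
  }
  key_dup(exposure, c("visit_id", "timepoint"), "exposure")
  key_dup(strain, c("visit_id", "timepoint"), "strain")
  key_dup(outcomes, c("visit_id", "timepoint"), "outcomes")
  key_dup(covariates, "visit_id", "covariates")

  if (nrow(outcomes) == 0) {
    warning("empty outcome table; returning an empty panel", call. = FALSE)
  } else {
    orphan <- setdiff(outcomes$visit_id, covariates$visit_id)
    if (length(orphan)) {
      stop("outcome visits without covariates: ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    }
  }

  panel <- outcomes |>
    dplyr::inner_join(exposure, by = c("visit_id", "timepoint")) |>
    dplyr::inner_join(strain, by = c("visit_id", "timepoint")) |>
    dplyr::inner_join(covariates, by = "visit_id") |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      visit_id = .data$visit_id, timepoint = .data$timepoint,
      outcome_fhr = .data$fhr, outcome_strain = .data$strain,
      stress_utci = .data$utci, stress_wbgt = .data$wbgt,
      heat_strain = .data$psi, fitness = .data$walk_m,
      fat_mass_pct = .data$fat_mass_pct, ga_weeks = .data$ga_weeks
    )
  complete <- stats::complete.cases(
    panel[c("outcome_fhr", "outcome_strain", "stress_utci", "stress_wbgt",
            "heat_strain", "fitness", "fat_mass_pct", "ga_weeks")])
  dropped <- sum(!complete)
  out <- panel[complete, ]
  attr(out, "audit") <- list(
    n_outcome_rows = nrow(outcomes), n_joined = nrow(panel),
    n_dropped_incomplete = dropped, n_final = nrow(out))
  out
}

.model_terms <- function(model_id) {
  switch(model_id,
    "1" = "heat_stress",
    "2" = c("heat_stress", "heat_strain"),
    "3" = c("heat_stress", "heat_strain", "fitness", "fat_mass_pct",
            "ga_weeks"),
    stop("`model_id` must be 1, 2 or 3", call. = FALSE))
}

#' Fit a total-effect or direct-effect repeated-measures model
#'
#' Fits one of three nested repeated-measures models of a fetal outcome on
#' heat stress, with the participant as the clustering unit:
#' model 1 regresses the outcome on heat stress alone (the total effect of
#' heat stress); model 2 adds maternal heat strain (the direct effect of heat
#' stress, holding strain fixed); model 3 additionally adjusts for
#' cardiovascular fitness, percentage fat mass and gestational age (the
#' direct effect of maternal heat strain). Outcome A is the continuous fetal
#' heart rate (linear model); outcome B is binary fetal strain (logistic
#' model, coefficients reported as odds ratios per 1 degree C of heat stress
#' and per PSI unit).
#'
#' The default estimator is a population-average cluster
#' estimating-equation fit with exchangeable working correlation and robust
#' standard errors ([gee_fit()]); `estimator = "glmm"` fits a
#' random-intercept mixed model instead (lme4), whose conditional estimates
#' differ from the marginal ones for logistic outcomes. A panel with a
#' single participant falls back to an ordinary fit with a warning.
#'
#' @param panel Panel from [build_panel()].
#' @param outcome `"A"` (fetal heart rate, linear) or `"B"` (fetal strain,
#'   logistic).
#' @param model_id 1, 2 or 3.
#' @param stress_index `"utci"` or `"wbgt"`.
#' @param estimator `"gee"` (default) or `"glmm"`.
#' @return Object of class `hs_fit`: tidy coefficient table (`terms`),
#'   information criterion (`aic`: QIC for the default estimator, true AIC
#'   for mixed models), sizes, and the underlying fit.
#' @export
fit_model <- function(panel, outcome = c("A", "B"), model_id = 1,
                      stress_index = c("utci", "wbgt"),
                      estimator = c("gee", "glmm")) {
  outcome <- match.arg(outcome)
  stress_index <- match.arg(stress_index)
  estimator <- match.arg(estimator)
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  dat <- as.data.frame(panel)
  dat$heat_stress <- dat[[paste0("stress_", stress_index)]]
  dat$y <- if (outcome == "A") dat$outcome_fhr else
    as.numeric(dat$outcome_strain)
  if (outcome == "B" && length(unique(dat$y)) < 2) {
    stop("fetal-strain outcome has a single class; logistic model ",
         "cannot be fitted", call. = FALSE)
  }
  rhs <- .model_terms(as.character(model_id))
  fam <- if (outcome == "A") "gaussian" else "binomial"

  if (estimator == "gee") {
    f <- stats::reformulate(rhs, response = "y")
    fit <- gee_fit(f, dat, id = "participant_id", family = fam)
    terms_tbl <- summary(fit)
    aic <- fit$qic
    n_clusters <- fit$n_clusters
  } else {
    f <- stats::reformulate(c(rhs, "(1 | participant_id)"), response = "y")
    fit <- if (outcome == "A") {
      lme4::lmer(f, data = dat, REML = FALSE)
    } else {
      lme4::glmer(f, data = dat, family = stats::binomial())
    }
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    z <- est / se
    terms_tbl <- tibble::tibble(
      term = names(est), estimate = unname(est), std_error = unname(se),
      statistic = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
      conf_low = unname(est - 1.959964 * se),
      conf_high = unname(est + 1.959964 * se))
    if (outcome == "B") {
      terms_tbl$or <- exp(terms_tbl$estimate)
      terms_tbl$or_low <- exp(terms_tbl$conf_low)
      terms_tbl$or_high <- exp(terms_tbl$conf_high)
    }
    aic <- stats::AIC(fit)
    n_clusters <- length(unique(dat$participant_id))
  }
  structure(list(
    model_id = as.integer(model_id), outcome = outcome,
    stress_index = stress_index, estimator = estimator,
    terms = terms_tbl, aic = aic,
    n_obs = nrow(dat), n_clusters = n_clusters, fit = fit
  ), class = "hs_fit")
}

#' @export
print.hs_fit <- function(x, ...) {
  cat(sprintf(
    "Model %d, outcome %s (%s), stress index %s, estimator %s\n",
    x$model_id, x$outcome,
    if (x$outcome == "A") "fetal heart rate, linear" else
      "fetal strain, logistic",
    toupper(x$stress_index), x$estimator))
  cat(sprintf("  n = %d observations in %d participants; %s = %.1f\n",
              x$n_obs, x$n_clusters,
              if (x$estimator == "gee") "QIC" else "AIC", x$aic))
  print(x$terms, n = Inf)
  invisible(x)
}

#' Fit the full set of effect models
#'
#' Convenience wrapper fitting models 1-3 for both outcomes and one or both
#' stress indices, returning the tidy stacked coefficient table (the layout
#' used for reporting total and direct effects side by side).
#'
#' @param panel Panel from [build_panel()].
#' @param stress_index Indices to fit (default both).
#' @param estimator Passed to [fit_model()].
#' @return Tibble with one row per model term per fitted model, including
#'   odds-ratio columns for the logistic models and the information
#'   criterion.
#' @export
fit_all_models <- function(panel, stress_index = c("utci", "wbgt"),
                           estimator = "gee") {
  grid <- expand.grid(outcome = c("A", "B"), model_id = 1:3,
                      idx = stress_index, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ft <- fit_model(panel, grid$outcome[i], grid$model_id[i], grid$idx[i],
                    estimator)
    tb <- ft$terms
    tb$outcome <- ft$outcome
    tb$model_id <- ft$model_id
    tb$stress_index <- ft$stress_index
    tb$aic <- ft$aic
    tb
  })
  dplyr::bind_rows(rows)
}

#' Compare linear and spline exposure-response shapes by AIC
#'
#' Fits the exposure term as (i) linear, (ii) a natural cubic spline with
#' interior knots at the empirical 50th and 90th centiles, and (iii) the same
#' natural spline on the log of the exposure (knots at the log-scale
#' centiles), and compares the fits by AIC. Random-intercept mixed models are
#' used (so a true likelihood-based AIC exists); ties within 1e-9 go to the
#' simpler shape (linear, then natural, then log spline).
#'
#' @inheritParams fit_model
#' @return Tibble with `shape`, `df`, `aic` and logical `winner`.
#' @export
spline_comparison <- function(panel, outcome = c("A", "B"),
                              stress_index = c("utci", "wbgt")) {
  outcome <- match.arg(outcome)
  stress_index <- match.arg(stress_index)
  dat <- as.data.frame(panel)
  dat$x <- dat[[paste0("stress_", stress_index)]]
  dat$y <- if (outcome == "A") dat$outcome_fhr else
    as.numeric(dat$outcome_strain)
  if (length(unique(dat$x)) < 3) {
    stop("degenerate exposure distribution (fewer than 3 distinct values)",
         call. = FALSE)
  }
  if (any(dat$x <= 0)) {
    stop("log-spline comparison requires positive exposures", call. = FALSE)
  }
  kn <- stats::quantile(dat$x, c(0.5, 0.9), names = FALSE)
  knl <- stats::quantile(log(dat$x), c(0.5, 0.9), names = FALSE)
  forms <- list(
    linear = y ~ x + (1 | participant_id),
    natural_spline =
      y ~ splines::ns(x, knots = kn) + (1 | participant_id),
    log_spline =
      y ~ splines::ns(log(x), knots = knl) + (1 | participant_id)
  )
  fits <- lapply(forms, function(f) {
    if (outcome == "A") lme4::lmer(f, data = dat, REML = FALSE) else
      lme4::glmer(f, data = dat, family = stats::binomial())
  })
  aics <- vapply(fits, stats::AIC, numeric(1))
  dfs <- vapply(fits, function(f) length(lme4::fixef(f)), numeric(1))
  # ties (within 1e-9) resolved toward the simpler shape: the list order is
  # simplest-first, so the first index attaining the minimum wins
  winner <- which(aics <= min(aics) + 1e-9)[1]
  tibble::tibble(shape = names(forms), df = unname(dfs), aic = unname(aics),
                 winner = seq_along(forms) == winner)
}

#' Paired baseline-versus-working Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of the within-visit change from baseline to the
#' working period (e.g. tympanic temperature, heart rate). Zero differences
#' are dropped (classical convention); the exact distribution is used for up
#' to 25 non-zero untied differences, otherwise the normal approximation with
#' continuity correction.
#'
#' @param baseline,working Paired numeric vectors of equal length (n >= 5).
#' @return List with `statistic` (V), `p_value`, `n_effective` (non-zero
#'   pairs) and `method`.
#' @export
paired_shift_test <- function(baseline, working) {
  stopifnot(length(baseline) == length(working))
  if (length(baseline) < 5) stop("need at least 5 pairs", call. = FALSE)
  d <- working - baseline
  d <- d[is.finite(d) & d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1, n_effective = 0L,
                method = "degenerate (all zero differences)"))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_effective = length(d),
       method = if (exact) "exact signed-rank" else
         "normal approximation with continuity correction")
}

#' Pearson correlation between two exposure indices
#'
#' @param x,y Numeric vectors (n >= 3, both non-constant).
#' @return List with `r`, `p_value` and `n`.
#' @export
index_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Sample size for comparing two proportions
#'
#' Classical normal-approximation sample size for detecting a difference
#' between an unexposed and an exposed incidence proportion at two-sided
#' level `alpha` and the given power, reported both without and with the
#' continuity correction (the two conventions bracket most published
#' calculators, so both are given rather than privileging one).
#'
#' @param p_unexposed,p_exposed Incidence proportions in (0, 1) (unequal).
#' @param alpha Two-sided type I error (default 0.05).
#' @param power Target power (default 0.80).
#' @return List with `n_per_group`, `n_total`, `n_per_group_corrected`,
#'   `n_total_corrected`.
#' @export
sample_size_two_proportions <- function(p_unexposed, p_exposed,
                                        alpha = 0.05, power = 0.80) {
  p <- c(p_unexposed, p_exposed)
  if (any(p <= 0 | p >= 1)) stop("proportions must be in (0, 1)",
                                 call. = FALSE)
  if (p_unexposed == p_exposed) {
    stop("proportions must differ", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must be in (0, 1)", call. = FALSE)
  }
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  pbar <- mean(p)
  delta <- abs(diff(p))
  n_raw <- (za * sqrt(2 * pbar * (1 - pbar)) +
            zb * sqrt(sum(p * (1 - p))))^2 / delta^2
  n_cc <- n_raw / 4 * (1 + sqrt(1 + 4 / (n_raw * delta)))^2
  list(n_per_group = ceiling(n_raw), n_total = 2 * ceiling(n_raw),
       n_per_group_corrected = ceiling(n_cc),
       n_total_corrected = 2 * ceiling(n_cc))
}

#' Model-assumption diagnostics
#'
#' Reports (without acting on) the standard residual checks for a fitted
#' effect model: a linearity check (quadratic term of residuals on fitted
#' values), homoscedasticity across exposure tertiles by Levene's test, and
#' a Shapiro-Wilk normality test of the residuals. With fewer than 10
#' residuals the report is flagged unreliable.
#'
#' @param fit An `hs_fit` from [fit_model()].
#' @param panel The panel the model was fitted on.
#' @return List with `linearity`, `levene`, `normality` (each a list with a
#'   statistic and p-value) and `unreliable`.
#' @export
model_diagnostics <- function(fit, panel) {
  r <- if (inherits(fit$fit, "hs_gee")) fit$fit$residuals else
    stats::residuals(fit$fit)
  fv <- if (inherits(fit$fit, "hs_gee")) fit$fit$fitted else
    stats::fitted(fit$fit)
  unreliable <- length(r) < 10
  lin <- tryCatch({
    lf <- stats::lm(r ~ fv + I(fv^2))
    cf <- summary(lf)$coefficients
    list(quadratic_estimate = cf["I(fv^2)", "Estimate"],
         p_value = cf["I(fv^2)", "Pr(>|t|)"])
  }, error = function(e) list(quadratic_estimate = NA_real_,
                              p_value = NA_real_))
  x <- panel[[paste0("stress_", fit$stress_index)]]
  lev <- tryCatch({
    tert <- cut(x, stats::quantile(x, c(0, 1 / 3, 2 / 3, 1)),
                include.lowest = TRUE)
    lt <- car::leveneTest(r ~ tert)
    list(statistic = lt[1, "F value"], p_value = lt[1, "Pr(>F)"])
  }, error = function(e) list(statistic = NA_real_, p_value = NA_real_))
  nor <- tryCatch({
    rr <- if (length(r) > 5000) r[seq(1, length(r), length.out = 5000)] else r
    st <- stats::shapiro.test(rr)
    list(statistic = unname(st$statistic), p_value = st$p.value)
  }, error = function(e) list(statistic = NA_real_, p_value = NA_real_))
  list(linearity = lin, levene = lev, normality = nor,
       unreliable = unreliable)
}
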