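# ---- file helpers ----------------------------------------------------------

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

.write_stage_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# heatstrain pipeline output",
               paste0("# seed: ", as.integer(config$seed)),
               paste0("# config_hash: ", .config_hash(config))), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

.read_stage_csv <- function(path) {
  if (!file.exists(path)) {
    stop("required input file is missing: ", path, call. = FALSE)
  }
  out <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) {
      stop("malformed CSV in ", basename(path), ": ", conditionMessage(e),
           call. = FALSE)
    })
  tibble::as_tibble(out)
}

# hours since shift start, from the ISO-8601 timestamps of one visit's rows
.t_hours_from_timestamps <- function(timestamp, visit_id) {
  tt <- as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  t0 <- stats::ave(as.numeric(tt), visit_id, FUN = min)
  (as.numeric(tt) - t0) / 3600
}

# ---- stages ----------------------------------------------------------------

.stage_simulate <- function(config, dir) {
  cohort <- generate_cohort(config)
  vi <- cohort$visits
  .write_stage_csv(cohort$participants, file.path(dir, "participants.csv"),
                   config)
  .write_stage_csv(
    vi[c("visit_id", "participant_id", "visit_number", "season", "date",
         "ga_weeks", "any_symptom")],
    file.path(dir, "visits.csv"), config)
  .write_stage_csv(cohort$baselines, file.path(dir, "baselines.csv"), config)
  ss <- cohort$shift_series
  .write_stage_csv(
    ss[c("visit_id", "timestamp", "ta_c", "rh_pct", "tg_c", "tnwb_c",
         "wind_ms", "hr_bpm", "tskin_c")],
    file.path(dir, "shift_series.csv"), config)
  fet <- cohort$fetal
  fet$visit_id <- vi$visit_id[fet$visit]
  .write_stage_csv(
    fet[c("visit_id", "timepoint", "fhr_mean", "ua_systolic_1",
          "ua_diastolic_1", "quality_1", "ua_systolic_2", "ua_diastolic_2",
          "quality_2")],
    file.path(dir, "fetal.csv"), config)
  fs <- cohort$fhr_series
  fs$visit_id <- vi$visit_id[fs$visit]
  .write_stage_csv(fs[c("visit_id", "timepoint", "time_min", "fhr_bpm")],
                   file.path(dir, "fhr_series.csv"), config)
  # observed activity log (cosmetic; drives the METs fallback)
  tasks <- default_met_table()$task
  nv <- nrow(vi)
  act <- tibble::tibble(
    visit_id = rep(vi$visit_id, each = 3),
    task = unlist(lapply(seq_len(nv), function(i)
      sample(tasks[tasks != "rest"], 3))),
    minutes = round(stats::runif(3 * nv, 40, 200)))
  .write_stage_csv(act, file.path(dir, "activities.csv"), config)
  c(visits = nrow(vi), shift_samples = nrow(ss), episodes = nrow(cohort$truth))
}

.stage_indices <- function(config, dir) {
  ss <- .read_stage_csv(file.path(dir, "shift_series.csv"))
  ss$t_hours <- .t_hours_from_timestamps(ss$timestamp, ss$visit_id)
  by_visit <- split(ss, ss$visit_id)
  exposure <- dplyr::bind_rows(
    lapply(by_visit, summarise_exposure), .id = "visit_id")
  .write_stage_csv(exposure, file.path(dir, "exposure.csv"), config)
  # episode-level heat stress: mean (or peak) exposure up to the timepoint
  red <- if (config$exposure_basis == "peak") max else mean
  tmrt <- mean_radiant_temperature(ss$tg_c, ss$ta_c, ss$wind_ms)
  ss$utci_c <- suppressWarnings(
    utci(ss$ta_c, tmrt, ss$wind_ms * 1.49, ss$rh_pct))
  ss$wbgt_c <- wbgt_outdoor(ss$tnwb_c, ss$tg_c, ss$ta_c)
  span <- stats::ave(ss$t_hours, ss$visit_id, FUN = max)
  eps <- lapply(c(mid = 0.5, end = 1), function(frac) {
    keep <- ss$t_hours <= span * frac
    tibble::tibble(
      visit_id = names(tapply(ss$utci_c[keep], ss$visit_id[keep], red)),
      utci = as.numeric(tapply(ss$utci_c[keep], ss$visit_id[keep], red)),
      wbgt = as.numeric(tapply(ss$wbgt_c[keep], ss$visit_id[keep], red)))
  })
  eps <- dplyr::bind_rows(eps, .id = "timepoint")
  eps <- eps[order(eps$visit_id, eps$timepoint),
             c("visit_id", "timepoint", "utci", "wbgt")]
  .write_stage_csv(eps, file.path(dir, "exposure_episodes.csv"), config)
  c(visits = nrow(exposure), episodes = nrow(eps))
}

.stage_strain <- function(config, dir) {
  ss <- .read_stage_csv(file.path(dir, "shift_series.csv"))
  bl <- .read_stage_csv(file.path(dir, "baselines.csv"))
  act_path <- file.path(dir, "activities.csv")
  act <- if (file.exists(act_path)) .read_stage_csv(act_path) else NULL
  ss$t_hours <- .t_hours_from_timestamps(ss$timestamp, ss$visit_id)
  ss$psi <- {
    i <- match(ss$visit_id, bl$visit_id)
    if (anyNA(i)) stop("shift series visit missing from baselines.csv",
                       call. = FALSE)
    as.numeric(psi_mod(ss$tskin_c, bl$tymp_c[i], ss$hr_bpm, bl$hr0_bpm[i]))
  }
  span <- stats::ave(ss$t_hours, ss$visit_id, FUN = max)
  rows <- lapply(c(mid = 0.5, end = 1), function(frac) {
    keep <- ss$t_hours <= span * frac
    agg <- function(f) as.numeric(tapply(ss$psi[keep], ss$visit_id[keep], f))
    ids <- names(tapply(ss$psi[keep], ss$visit_id[keep], max))
    last <- tapply(seq_len(nrow(ss))[keep], ss$visit_id[keep],
                   function(ix) ix[length(ix)])
    tibble::tibble(visit_id = ids, psi = ss$psi[as.integer(last)],
                   peak_psi = agg(max), mean_psi = agg(mean))
  })
  st <- dplyr::bind_rows(rows, .id = "timepoint")
  mets <- if (!is.null(act)) {
    vapply(split(act, act$visit_id), mets_method_b, numeric(1))
  } else NULL
  st$mets_final <- if (is.null(mets)) NA_real_ else
    unname(mets[st$visit_id])
  st$provenance <- ifelse(is.na(st$mets_final), NA_character_, "B")
  st <- st[order(st$visit_id, st$timepoint),
           c("visit_id", "timepoint", "psi", "peak_psi", "mean_psi",
             "mets_final", "provenance")]
  .write_stage_csv(st, file.path(dir, "strain.csv"), config)
  c(episodes = nrow(st))
}

.stage_fetal <- function(config, dir) {
  fet <- .read_stage_csv(file.path(dir, "fetal.csv"))
  fs <- .read_stage_csv(file.path(dir, "fhr_series.csv"))
  vi <- .read_stage_csv(file.path(dir, "visits.csv"))
  fet$visit <- fet$visit_id
  fs$visit <- fs$visit_id
  visits <- tibble::tibble(visit = vi$visit_id, ga_weeks = vi$ga_weeks)
  cls <- classify_episodes(fet, fs, visits,
                           ri_eligible_weeks = config$ri_eligible_weeks)
  names(cls)[names(cls) == "visit"] <- "visit_id"
  .write_stage_csv(cls, file.path(dir, "strain_outcomes.csv"), config)
  c(episodes = nrow(cls), strained = sum(cls$fetal_strain))
}

.stage_fit <- function(config, dir, stress_index = c("utci", "wbgt"),
                       estimator = "gee") {
  eps <- .read_stage_csv(file.path(dir, "exposure_episodes.csv"))
  st <- .read_stage_csv(file.path(dir, "strain.csv"))
  so <- .read_stage_csv(file.path(dir, "strain_outcomes.csv"))
  fet <- .read_stage_csv(file.path(dir, "fetal.csv"))
  vi <- .read_stage_csv(file.path(dir, "visits.csv"))
  pa <- .read_stage_csv(file.path(dir, "participants.csv"))
  work <- fet[fet$timepoint != "baseline", ]
  outcomes <- tibble::tibble(
    visit_id = work$visit_id, timepoint = work$timepoint,
    fhr = work$fhr_mean)
  key <- paste(so$visit_id, so$timepoint)
  outcomes$strain <- so$fetal_strain[
    match(paste(outcomes$visit_id, outcomes$timepoint), key)]
  covariates <- dplyr::left_join(
    vi[c("visit_id", "participant_id", "ga_weeks")],
    pa[c("participant_id", "fat_mass_pct", "walk_m")],
    by = "participant_id")
  panel <- build_panel(eps, st[c("visit_id", "timepoint", "mean_psi")] |>
                         dplyr::rename(psi = "mean_psi"),
                       outcomes, covariates)
  fits <- fit_all_models(panel, stress_index = stress_index,
                         estimator = estimator)
  jsonlite::write_json(fits, file.path(dir, "fits.json"), digits = NA,
                       dataframe = "rows")
  c(panel_rows = nrow(panel), models = length(unique(
    paste(fits$outcome, fits$model_id, fits$stress_index))))
}

.stage_report <- function(config, dir) {
  fits <- tibble::as_tibble(
    jsonlite::read_json(file.path(dir, "fits.json"), simplifyVector = TRUE))
  fmt <- function(df) {
    has_or <- if ("or" %in% names(df)) !is.na(df$or) else
      rep(FALSE, nrow(df))
    ifelse(has_or,
           sprintf("OR %.2f (%.2f-%.2f)",
                   df$or, df$or_low, df$or_high),
           sprintf("%.2f (%.2f-%.2f)",
                   df$estimate, df$conf_low, df$conf_high))
  }
  keep <- fits$term %in% c("heat_stress", "heat_strain")
  tb <- fits[keep, ]
  tb$label <- ifelse(tb$term == "heat_stress",
                     toupper(tb$stress_index), "PSI")
  tb$cell <- fmt(tb)
  out <- NULL
  for (oc in unique(tb$outcome)) {
    for (ix in unique(tb$stress_index)) {
      sub <- tb[tb$outcome == oc & tb$stress_index == ix, ]
      for (lab in unique(sub$label)) {
        row <- list(outcome = oc, stress_index = ix, term = lab)
        for (m in 1:3) {
          s <- sub[sub$label == lab & sub$model_id == m, ]
          row[[paste0("model", m)]] <-
            if (nrow(s)) s$cell[1] else ""
          row[[paste0("p", m)]] <-
            if (nrow(s)) signif(s$p_value[1], 2) else NA_real_
        }
        out <- dplyr::bind_rows(out, tibble::as_tibble(row))
      }
      aics <- vapply(1:3, function(m) {
        a <- unique(tb$aic[tb$outcome == oc & tb$stress_index == ix &
                             tb$model_id == m])
        if (length(a)) round(a[1], 1) else NA_real_
      }, numeric(1))
      out <- dplyr::bind_rows(out, tibble::tibble(
        outcome = oc, stress_index = ix, term = "AIC",
        model1 = as.character(aics[1]), p1 = NA_real_,
        model2 = as.character(aics[2]), p2 = NA_real_,
        model3 = as.character(aics[3]), p3 = NA_real_))
    }
  }
  .write_stage_csv(out, file.path(dir, "table2.csv"), config)
  c(rows = nrow(out))
}

# ---- orchestration ---------------------------------------------------------

.stage_deps <- list(
  simulate = character(0),
  indices = "shift_series.csv",
  strain = c("shift_series.csv", "baselines.csv"),
  fetal = c("fetal.csv", "fhr_series.csv", "visits.csv"),
  fit = c("exposure_episodes.csv", "strain.csv", "strain_outcomes.csv",
          "fetal.csv", "visits.csv", "participants.csv"),
  report = "fits.json")

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: `simulate` (synthetic
#' cohort to CSV), `indices` (thermal exposure summaries), `strain`
#' (maternal PSI and METs), `fetal` (composite fetal-strain classification),
#' `fit` (repeated-measures effect models to `fits.json`) and `report` (the
#' side-by-side total/direct-effect table `table2.csv`). A run manifest
#' (seed, configuration hash, per-stage row counts, warnings) is written to
#' `manifest.yaml` and returned.
#'
#' @param config A [cohort_config()]; its seed governs the whole run.
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to run (default all, in order).
#' @param stress_index,estimator Passed to the fitting stage.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         stages = c("simulate", "indices", "strain",
                                    "fetal", "fit", "report"),
                         stress_index = c("utci", "wbgt"),
                         estimator = "gee") {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  warnings <- character(0)
  for (st in stages) {
    missing_dep <- .stage_deps[[st]][
      !file.exists(file.path(out_dir, .stage_deps[[st]]))]
    if (length(missing_dep)) {
      stop("stage `", st, "` requires ", paste(missing_dep, collapse = ", "),
           " (enable the producing stage or provide the file)",
           call. = FALSE)
    }
    res <- withCallingHandlers(
      tryCatch(
        switch(st,
          simulate = .stage_simulate(config, out_dir),
          indices = .stage_indices(config, out_dir),
          strain = .stage_strain(config, out_dir),
          fetal = .stage_fetal(config, out_dir),
          fit = .stage_fit(config, out_dir, stress_index, estimator),
          report = .stage_report(config, out_dir)),
        error = function(e) {
          stop("stage `", st, "` failed: ", conditionMessage(e),
               call. = FALSE)
        }),
      warning = function(w) {
        warnings <<- c(warnings, paste0(st, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    counts[[st]] <- as.list(res)
  }
  manifest <- list(
    config_hash = .config_hash(config),
    seed = as.integer(config$seed),
    stages = stages,
    counts = counts,
    warnings = warnings)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

# per-file schema and range checks used by validate_inputs()
.file_checks <- list(
  shift_series.csv = function(df) {
    v <- list()
    need <- c("visit_id", "timestamp", "ta_c", "rh_pct", "tg_c", "tnwb_c",
              "wind_ms", "hr_bpm", "tskin_c")
    miss <- setdiff(need, names(df))
    if (length(miss)) v <- c(v, paste("missing column(s):",
                                      paste(miss, collapse = ", ")))
    if ("rh_pct" %in% names(df) && any(df$rh_pct < 0 | df$rh_pct > 100)) {
      v <- c(v, "rh_pct outside [0, 100]")
    }
    if ("wind_ms" %in% names(df) && any(df$wind_ms < 0)) {
      v <- c(v, "negative wind_ms")
    }
    if ("hr_bpm" %in% names(df) && any(df$hr_bpm < 40 | df$hr_bpm > 220)) {
      v <- c(v, "hr_bpm outside [40, 220]")
    }
    v
  },
  exposure.csv = function(df) {
    v <- list()
    if ("visit_id" %in% names(df) && anyDuplicated(df$visit_id)) {
      v <- c(v, "duplicate visit_id")
    }
    if (all(c("wbgt_mean", "wbgt_peak") %in% names(df)) &&
        any(df$wbgt_peak < df$wbgt_mean - 1e-9)) {
      v <- c(v, "wbgt_peak below wbgt_mean")
    }
    v
  },
  strain.csv = function(df) {
    v <- list()
    if (all(c("visit_id", "timepoint") %in% names(df)) &&
        anyDuplicated(df[c("visit_id", "timepoint")])) {
      v <- c(v, "duplicate (visit_id, timepoint)")
    }
    if (all(c("peak_psi", "mean_psi") %in% names(df)) &&
        any(df$peak_psi < df$mean_psi - 1e-9)) {
      v <- c(v, "peak_psi below mean_psi")
    }
    v
  },
  fetal.csv = function(df) {
    v <- list()
    for (s in 1:2) {
      sy <- df[[paste0("ua_systolic_", s)]]
      di <- df[[paste0("ua_diastolic_", s)]]
      if (!is.null(sy) && !is.null(di)) {
        bad <- is.finite(sy) & is.finite(di) & (sy <= 0 | di < 0 | di > sy)
        if (any(bad)) v <- c(v, paste0("implausible Doppler velocities in ",
                                       "reading ", s))
      }
    }
    v
  }
)

#' Validate pipeline input/output files
#'
#' Schema, unit-range and key-integrity checks over the pipeline's CSV
#' contracts (shift series, exposure, strain, fetal tables). Unknown files
#' are skipped with a note.
#'
#' @param files Character vector of file paths (or a directory, which is
#'   expanded to the known files it contains).
#' @return Tibble with columns `file`, `status` (`"ok"`/`"violation"`/
#'   `"error"`) and `detail`; zero `"violation"`/`"error"` rows means a
#'   clean set.
#' @export
validate_inputs <- function(files) {
  if (length(files) == 1 && dir.exists(files)) {
    files <- file.path(files, intersect(names(.file_checks),
                                        list.files(files)))
  }
  out <- list()
  for (f in files) {
    nm <- basename(f)
    res <- tryCatch({
      df <- .read_stage_csv(f)
      if (is.null(.file_checks[[nm]])) {
        tibble::tibble(file = nm, status = "ok",
                       detail = "no checks registered for this file")
      } else {
        v <- .file_checks[[nm]](df)
        if (length(v) == 0) {
          tibble::tibble(file = nm, status = "ok", detail = "")
        } else {
          tibble::tibble(file = nm, status = "violation",
                         detail = unlist(v))
        }
      }
    }, error = function(e) {
      tibble::tibble(file = nm, status = "error",
                     detail = conditionMessage(e))
    })
    out[[f]] <- res
  }
  dplyr::bind_rows(out)
}
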