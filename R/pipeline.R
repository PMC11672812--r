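# tiny polynomial rolling hash over a deparsed object; labels every
# artifact with the config that produced it
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Tuned boosted-model specs per age group
#'
#' Gradient-boosting hyperparameters used for chart retraining: squared
#' error loss with learning rate/estimators/depth of 0.09/95/2 (newborn),
#' 0.06/91/3 (cub) and 0.14/93/4 (sub-adult/adult).
#'
#' @return Named list of [model_spec()]s.
#' @export
default_group_specs <- function() {
  list(newborn = model_spec("gbdt", loss = "ls", learning_rate = 0.09,
                            n_estimators = 95, max_depth = 2),
       cub = model_spec("gbdt", loss = "ls", learning_rate = 0.06,
                        n_estimators = 91, max_depth = 3),
       subadult_adult = model_spec("gbdt", loss = "ls", learning_rate = 0.14,
                                   n_estimators = 93, max_depth = 4))
}

#' Default end-to-end pipeline configuration
#'
#' @param records Optional path to an input records CSV; when `NULL` a
#'   synthetic cohort is simulated.
#' @param sim A [sim_config()] used when simulating.
#' @param seed Master seed; stage seeds derive from it.
#' @param bootstrap_B Bootstrap replicates for the chart stage.
#' @param chart_max_age Named per-sex last chart day.
#' @param specs Per-age-group [model_spec()]s for chart retraining.
#' @return A list of class `run_config`.
#' @export
run_config <- function(records = NULL, sim = sim_config(), seed = 1L,
                       bootstrap_B = 1000,
                       chart_max_age = c(female = 13717, male = 11984),
                       specs = default_group_specs()) {
  structure(list(records = records, sim = sim, seed = seed,
                 bootstrap_B = bootstrap_B, chart_max_age = chart_max_age,
                 specs = specs), class = "run_config")
}

write_stage <- function(df, dir, name, hash) {
  path <- file.path(dir, name)
  utils::write.csv(cbind(df, config_hash = hash), path, row.names = FALSE)
  path
}

#' Run the full weight-for-age pipeline
#'
#' Simulates (or loads) records, applies the feeding-status calibration,
#' cross-validates the candidate models per age group, retrains the tuned
#' boosted models under the bootstrap, builds the per-day chart, and runs
#' the seasonal/reproductive and velocity statistics. All artifacts are
#' written under `out_dir` together with a run manifest (config hash,
#' seeds, versions, stage counts).
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory artifacts and the manifest.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = tempfile("pandagrowth-"),
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(cfg))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  rs <- stage("input", {
    if (is.null(cfg$records)) simulate_cohort(cfg$sim)$records
    else load_records(cfg$records)
  })
  write_records(rs, file.path(out_dir, "records.csv"))

  cal <- stage("calibrate", calibrate_records(rs, seed = cfg$seed))
  write_records(cal$records, file.path(out_dir, "calibrated.csv"))
  jsonlite::write_json(
    list(config_hash = hash,
         per_sex = lapply(cal$report$per_sex, function(s)
           s[c("mean_distance", "sd_distance", "n_months", "n_removed",
               "n_kept", "n_months_skipped")]),
         curve_params = lapply(cal$fits, function(f) as.list(f$params))),
    file.path(out_dir, "calibration_report.json"),
    auto_unbox = TRUE, digits = NA)

  grp <- assign_age_group(cal$records$age_days)
  cv_tables <- stage("cross-validate", {
    lapply(levels(grp), function(g) {
      sub <- cal$records[grp == g, , drop = FALSE]
      if (nrow(sub) < 25) return(NULL)
      cv <- cross_validate_models(split_train_test(sub, seed = cfg$seed)$train,
                                  seed = cfg$seed)
      cv$age_group <- g
      cv
    })
  })
  cv_table <- do.call(rbind, cv_tables)
  write_stage(cv_table, out_dir, "cv_table.csv", hash)

  chart <- stage("chart", weight_chart(cal$records, cfg$specs,
                                       B = cfg$bootstrap_B,
                                       max_age_days = cfg$chart_max_age,
                                       seed = cfg$seed))
  write_stage(as.data.frame(chart), out_dir, "chart.csv", hash)

  stats_out <- stage("stats", {
    adults <- filter_adults(cal$records)
    comps <- list()
    for (s in c("female", "male")) {
      sub <- adults[as.character(adults$sex) == s, , drop = FALSE]
      if (nrow(sub) == 0) next
      for (sch in c("natural_season", "reproductive")) {
        cmp <- compare_periods(sub, period_scheme(sch))
        if (is.null(cmp)) next
        cmp$sex <- s; cmp$scheme <- sch
        comps[[paste(s, sch)]] <- cmp
      }
    }
    vel_a <- velocity_from_records(cal$records)
    vel_b <- velocity_from_chart(chart)
    vel_cmp <- compare_velocity_by_sex(
      vel_a[vel_a$age_mid_days <= 2008, , drop = FALSE])
    list(comparisons = do.call(rbind, comps),
         velocities = rbind(vel_a, vel_b), velocity_by_sex = vel_cmp)
  })
  write_stage(stats_out$comparisons, out_dir, "comparisons.csv", hash)
  write_stage(stats_out$velocities, out_dir, "velocities.csv", hash)
  write_stage(stats_out$velocity_by_sex, out_dir, "velocity_by_sex.csv", hash)

  manifest <- list(
    config_hash = hash, seed = cfg$seed,
    package_version = as.character(utils::packageVersion("pandagrowth")),
    r_version = R.version.string,
    counts = list(records_in = nrow(rs),
                  clustered = sum(vapply(cal$report$per_sex, `[[`, 0L,
                                         "n_clustered")),
                  removed = sum(vapply(cal$report$per_sex, `[[`, 0L,
                                       "n_removed")),
                  kept = sum(vapply(cal$report$per_sex, `[[`, 0L, "n_kept")),
                  calibrated = nrow(cal$records),
                  chart_rows = nrow(chart)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(records = rs, calibration = cal, cv = cv_table,
                 chart = chart, stats = stats_out, manifest = manifest,
                 out_dir = out_dir))
}
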