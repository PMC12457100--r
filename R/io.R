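#' Read a cohort CSV
#'
#' Long format with columns `subject_id, group, day, volume_mm3`; times in
#' days with the day origin at each subject's first observation, volumes in
#' mm^3.
#'
#' @param path CSV file path.
#' @return A list of [subject_record()]s, named by subject.
#' @export
read_cohort_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "day", "volume_mm3")
  missing <- setdiff(needed, names(dat))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  recs <- lapply(split(dat, dat$subject_id), function(d) {
    d <- d[order(d$day), ]
    subject_record(d$subject_id[1], d$group[1], d$day, d$volume_mm3)
  })
  recs[order(names(recs))]
}

#' Write a cohort CSV
#'
#' @param records list of [subject_record()]s or a long-format data.frame
#'   with the standard columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  dat <- if (is.data.frame(records)) records else
    do.call(rbind, lapply(records, function(r) {
      data.frame(subject_id = r$subject_id, group = r$group, day = r$times,
                 volume_mm3 = r$volumes)
    }))
  utils::write.csv(dat, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory CSV
#'
#' Columns `time_d, T, P1, P2, A, TD, MD, volume_mm3`.
#'
#' @param traj a `population_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML (or JSON) configuration with optional blocks `params` (field
#' overrides for [model_params()]), `schedule`
#' (`ir_start_day, n_fractions, interval_days, S_T`), `therapies` (list of
#' `{id, start, end, settings...}`), `cohort` (overrides for
#' [cohort_spec()]), `solver` (`rtol, atol`), `seed`, and `horizon`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A named list of class `run_config` with resolved components.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  structure(resolve_config(raw), class = "run_config")
}

resolve_config <- function(raw) {
  cfg <- list(seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
              horizon = raw$horizon)
  cfg$solver <- do.call(solver_control, as.list(raw$solver))
  cfg$params <- do.call(model_params, as.list(raw$params))
  sch <- raw$schedule
  cfg$therapies <- lapply(raw$therapies, config_therapy)
  if (!is.null(sch)) {
    cfg$schedule <- ir_course(
      start_day = if (is.null(sch$ir_start_day)) 1 else sch$ir_start_day,
      n_fractions = if (is.null(sch$n_fractions)) 5 else sch$n_fractions,
      interval_days = if (is.null(sch$interval_days)) 1 else
        sch$interval_days,
      S_T = if (is.null(sch$S_T)) 0.5 else sch$S_T,
      therapies = cfg$therapies)
  } else {
    cfg$schedule <- schedule(therapies = cfg$therapies)
  }
  co <- as.list(raw$cohort)
  co$params <- cfg$params
  if (!is.null(raw$seed) && is.null(co$seed)) co$seed <- cfg$seed
  cfg$cohort <- do.call(cohort_spec, co)
  cfg
}

config_therapy <- function(th) {
  id <- th$id
  win <- c(if (is.null(th$start)) 0 else th$start,
           if (is.null(th$end)) Inf else th$end)
  switch(id,
    anti_cd47 = anti_cd47(
      multiplier = if (is.null(th$multiplier)) 3 else th$multiplier,
      window = win),
    alpha_cd49d = alpha_cd49d(
      attenuation = if (is.null(th$attenuation)) 0 else th$attenuation,
      window = win),
    csf1r = csf1r_inhibitor(
      mu_multiplier = if (is.null(th$mu_multiplier)) 3 else
        th$mu_multiplier,
      attenuation = if (is.null(th$attenuation)) 0 else th$attenuation,
      lambda_override = th$lambda_override,
      window = if (is.null(th$end)) NULL else win,
      start = if (is.null(th$start)) 0 else th$start),
    stop("unknown therapy id: ", id, call. = FALSE))
}

assumption_notice <- function(run_label) {
  message("[", run_label, "] note: biomarker panel formulas and therapy ",
          "effect magnitudes (anti-CD47 multiplier, CSF-1R settings) are ",
          "package defaults documented in the methods vignette, not ",
          "literature-fixed values.")
}

#' Generate a synthetic cohort from a config
#'
#' Writes `cohort.csv` and `truth.csv` into `out_dir`.
#'
#' @param config a `run_config` (see [read_run_config()]) or config path.
#' @param out_dir output directory (created if missing).
#' @return The `synthetic_cohort`, invisibly.
#' @export
run_synth <- function(config, out_dir) {
  cfg <- as_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assumption_notice("synth")
  cohort <- generate_cohort(cfg$cohort)
  write_cohort_csv(cohort$records, file.path(out_dir, "cohort.csv"))
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(cohort)
}

#' Fit a cohort CSV from a config
#'
#' Writes `fit_report.csv` (subject_id, group, rho_T, S_T, rmse, n_points,
#' converged) into `out_dir`.
#'
#' @param config a `run_config` or config path.
#' @param cohort_csv path to a cohort CSV.
#' @param out_dir output directory.
#' @return The `cohort_fit`, invisibly.
#' @export
run_fit <- function(config, cohort_csv, out_dir) {
  cfg <- as_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assumption_notice("fit")
  records <- read_cohort_csv(cohort_csv)
  fit <- fit_cohort(records, fixed = cfg$params,
                    schedule_template = cfg$schedule,
                    control = cfg$solver)
  utils::write.csv(fit$report, file.path(out_dir, "fit_report.csv"),
                   row.names = FALSE)
  invisible(fit)
}

#' Simulate one subject from a config
#'
#' Simulates the configured schedule from an initial volume and writes
#' `trajectory.csv`.
#'
#' @param config a `run_config` or config path.
#' @param V0 initial volume (mm^3).
#' @param out_dir output directory.
#' @return The `population_trajectory`, invisibly.
#' @export
run_simulate <- function(config, V0 = 3, out_dir) {
  cfg <- as_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assumption_notice("simulate")
  horizon <- if (is.null(cfg$horizon)) 30 else cfg$horizon
  init <- allocate_initial_state(V0, initial_fractions(), cfg$params)
  tr <- simulate_population(init, cfg$params, cfg$schedule,
                            horizon = horizon, control = cfg$solver)
  write_trajectory_csv(tr, file.path(out_dir, "trajectory.csv"))
  invisible(tr)
}

#' Run a paired digital-twin trial from a config
#'
#' Builds ground-truth twins from the configured synthetic cohort, runs
#' the configured schedule (arm B) against no treatment (arm A), and
#' writes `trial_report.json` and `km_curves.csv`.
#'
#' @param config a `run_config` or config path.
#' @param out_dir output directory.
#' @param horizon simulation horizon (days); defaults to 3 times the
#'   latest observation time in the cohort.
#' @return The `trial_result`, invisibly.
#' @export
run_trial_config <- function(config, out_dir, horizon = NULL) {
  cfg <- as_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assumption_notice("trial")
  cohort <- generate_cohort(cfg$cohort)
  twins <- twins_from_truth(cohort, "treated")
  if (is.null(horizon)) {
    horizon <- if (!is.null(cfg$horizon)) cfg$horizon else
      3 * max(cohort$data$day)
  }
  arm_b <- per_twin_S_T(cfg$schedule)
  res <- run_trial(twins, schedule(), arm_b, horizon = horizon,
                   control = cfg$solver)
  write_trial_json(res, file.path(out_dir, "trial_report.json"))
  km <- rbind(cbind(arm = "A", res$km_a), cbind(arm = "B", res$km_b))
  utils::write.csv(km, file.path(out_dir, "km_curves.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Biomarker panels for a synthetic cohort from a config
#'
#' Writes `biomarkers.csv` with one row per subject and epoch.
#'
#' @param config a `run_config` or config path.
#' @param out_dir output directory.
#' @return The panel data.frame, invisibly.
#' @export
run_biomarkers <- function(config, out_dir) {
  cfg <- as_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assumption_notice("biomarkers")
  cohort <- generate_cohort(cfg$cohort)
  pan <- generate_biomarker_groups(cohort, seed = cfg$seed)
  utils::write.csv(pan, file.path(out_dir, "biomarkers.csv"),
                   row.names = FALSE)
  invisible(pan)
}

write_trial_json <- function(res, path) {
  jsonlite::write_json(list(
    subjects = res$subject_id,
    death_a = res$death_a, death_b = res$death_b,
    censored_a = res$censored_a, censored_b = res$censored_b,
    gains = res$gains, median_gain = res$median_gain,
    median_a = res$median_a, median_b = res$median_b,
    logrank_statistic = res$logrank$statistic,
    logrank_p = res$logrank$p_value,
    horizon = res$horizon), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config else read_run_config(config)
}
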