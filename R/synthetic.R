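#' Specification of a synthetic virtual cohort
#'
#' The generator emulates the statistical structure of the small-animal
#' study the model targets: a handful of untreated animals with early
#' (~3 mm^3) tumors, a larger irradiated group first observed at much
#' larger volumes (mean 41.5 mm^3), sparse irregular sampling with 4-7
#' time points per subject, inter-subject heterogeneity concentrated in the
#' tumor proliferation rate, heterogeneous radiosensitivity, and
#' multiplicative lognormal measurement noise.
#'
#' The two groups have separate proliferation-rate distributions because
#' they live in different killing-rate regimes (see [mu_preset()]): the
#' balance against the strong early-tumor killing in controls requires
#' proliferation coefficients orders of magnitude above those of the
#' large, immunosuppressed irradiated tumors.
#'
#' @param n_control number of untreated subjects (default 4).
#' @param n_treated number of irradiated subjects (default 10).
#' @param rho_T_control `c(median, sdlog)` of the lognormal control
#'   proliferation-rate distribution.
#' @param rho_T_treated `c(median, sdlog)` for the treated group.
#' @param S_T_range uniform range of the per-fraction tumor survival
#'   fraction.
#' @param v0_control `c(median, sdlog)` of the lognormal initial-volume
#'   distribution of controls (median ~3 mm^3).
#' @param v0_treated_mean,v0_treated_sdlog lognormal initial-volume
#'   distribution of treated subjects, parameterized by its mean
#'   (41.5 mm^3) and log-sd.
#' @param n_points_range integer range of observation counts per subject.
#' @param followup_control,followup_treated length (days) of the sampling
#'   window after the first observation.
#' @param noise_sd sd of the multiplicative lognormal measurement noise
#'   (0.1 = ~10% volumetric error; 0 = noiseless).
#' @param params shared fixed [model_params()] (killing-rate presets are
#'   applied per group).
#' @param ir_start_day,n_fractions,interval_days the irradiation course
#'   administered to the treated group, relative to first observation.
#' @param seed RNG seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 4, n_treated = 10,
                        rho_T_control = c(1.6e-4, 0.12),
                        rho_T_treated = c(6e-7, 0.3),
                        S_T_range = c(0.45, 0.7),
                        v0_control = c(3, 0.25),
                        v0_treated_mean = 41.5, v0_treated_sdlog = 0.35,
                        n_points_range = c(4L, 7L),
                        followup_control = 8, followup_treated = 22,
                        noise_sd = 0.1,
                        params = model_params(),
                        ir_start_day = 1, n_fractions = 5,
                        interval_days = 1,
                        seed = 1L) {
  stopifnot(n_control >= 0, n_treated >= 0,
            S_T_range[1] > 0, S_T_range[2] <= 1,
            S_T_range[1] <= S_T_range[2],
            n_points_range[1] >= 3, noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject `(rho_T, S_T, V0)` from the spec's distributions,
#' simulates the true model per subject (controls untreated; treated
#' subjects under the spec's irradiation course), samples volumes at
#' irregular times, applies multiplicative noise, and returns long-format
#' records plus a ground-truth table for recovery tests.
#'
#' Treated initial states are allocated exactly as the fitting pipeline
#' allocates them: proportion regressions are built from the true control
#' trajectories, and each treated subject's first volume is expressed
#' relative to the maximum observed control volume.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `records` (list of
#'   [subject_record()]), `data` (long-format data.frame with columns
#'   `subject_id, group, day, volume_mm3`), `truth` (data.frame with
#'   `subject_id, group, true_rho_T, true_S_T, V0, last_true_volume,
#'   death_threshold`), `trajectories` (true `population_trajectory` per
#'   subject), `maps`, `ref_max_volume`, `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  p_c <- update_params(spec$params, mu = mu_preset("control"))
  p_t <- update_params(spec$params, mu = mu_preset("treated"))
  fr0 <- initial_fractions()

  records <- list()
  trajs <- list()
  truth <- list()

  sample_times <- function(followup) {
    k <- sample(seq(spec$n_points_range[1], spec$n_points_range[2]), 1)
    c(0, sort(stats::runif(k - 1, min = 0.1 * followup, max = followup)))
  }
  noisy <- function(v) {
    if (spec$noise_sd > 0) v * exp(stats::rnorm(length(v), 0,
                                                spec$noise_sd)) else v
  }

  draws_c <- draw_subject_parameters(spec, spec$n_control, "control")
  draws_t <- draw_subject_parameters(spec, spec$n_treated, "treated")

  for (i in seq_len(spec$n_control)) {
    id <- sprintf("C%02d", i)
    rho <- draws_c$rho_T[i]
    V0 <- draws_c$V0[i]
    tt <- sample_times(spec$followup_control)
    p <- update_params(p_c, rho_T = rho)
    init <- allocate_initial_state(V0, fr0, p)
    tr <- simulate_population(init, p, NULL, horizon = max(tt),
                              output_grid =
                                sort(unique(c(seq(0, max(tt),
                                                  length.out = 201L), tt))))
    v_true <- volume_at(tr, tt)
    records[[id]] <- subject_record(id, "control", tt, noisy(v_true))
    trajs[[id]] <- tr
    truth[[id]] <- data.frame(subject_id = id, group = "control",
                              true_rho_T = rho, true_S_T = NA_real_,
                              V0 = V0,
                              last_true_volume = v_true[length(v_true)],
                              death_threshold =
                                1.2 * max(v_true[length(v_true)], V0))
  }

  maps <- NULL
  ref_max <- NA_real_
  if (spec$n_treated > 0) {
    if (spec$n_control < 2) {
      stop("treated subjects require >= 2 controls for the proportion maps",
           call. = FALSE)
    }
    maps <- proportion_regression(trajs)
    ref_max <- max(vapply(records, function(r) max(r$volumes), numeric(1)))
  }

  for (i in seq_len(spec$n_treated)) {
    id <- sprintf("T%02d", i)
    rho <- draws_t$rho_T[i]
    S_T <- draws_t$S_T[i]
    V0 <- draws_t$V0[i]
    tt <- sample_times(spec$followup_treated)
    fr <- predict_fractions(maps, V0 / ref_max)
    p <- update_params(p_t, rho_T = rho)
    init <- allocate_initial_state(V0, fr, p)
    sch <- ir_course(start_day = spec$ir_start_day,
                     n_fractions = spec$n_fractions,
                     interval_days = spec$interval_days, S_T = S_T)
    tr <- simulate_population(init, p, sch, horizon = max(tt),
                              output_grid =
                                sort(unique(c(seq(0, max(tt),
                                                  length.out = 201L), tt))))
    v_true <- volume_at(tr, tt)
    records[[id]] <- subject_record(id, "treated", tt, noisy(v_true))
    trajs[[id]] <- tr
    truth[[id]] <- data.frame(subject_id = id, group = "treated",
                              true_rho_T = rho, true_S_T = S_T, V0 = V0,
                              last_true_volume = v_true[length(v_true)],
                              death_threshold =
                                1.2 * max(v_true[length(v_true)], V0))
  }

  # threshold rule: 20% above the final true sampled volume, kept above
  # the initial volume so a twin cannot be dead at t = 0
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  data <- do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = r$subject_id, group = r$group, day = r$times,
               volume_mm3 = r$volumes)
  }))
  rownames(data) <- NULL
  structure(list(records = records, data = data, truth = truth,
                 trajectories = trajs, maps = maps,
                 ref_max_volume = ref_max, spec = spec),
            class = "synthetic_cohort")
}

#' Draw per-subject parameters from a cohort spec
#'
#' The sampling step of [generate_cohort()], exposed so the distributional
#' structure of a spec can be examined at any sample size without
#' simulating trajectories. Uses the current RNG stream.
#'
#' @param spec a [cohort_spec()].
#' @param n number of subjects to draw.
#' @param group `"control"` or `"treated"`.
#' @return A data.frame with `rho_T` (lognormal around the group median),
#'   `S_T` (uniform; `NA` for controls) and `V0` (lognormal).
#' @export
draw_subject_parameters <- function(spec, n,
                                    group = c("control", "treated")) {
  group <- match.arg(group)
  if (n == 0) {
    return(data.frame(rho_T = numeric(0), S_T = numeric(0),
                      V0 = numeric(0)))
  }
  if (group == "control") {
    data.frame(
      rho_T = spec$rho_T_control[1] *
        exp(stats::rnorm(n, 0, spec$rho_T_control[2])),
      S_T = NA_real_,
      V0 = spec$v0_control[1] * exp(stats::rnorm(n, 0, spec$v0_control[2])))
  } else {
    meanlog <- log(spec$v0_treated_mean) - spec$v0_treated_sdlog^2 / 2
    data.frame(
      rho_T = spec$rho_T_treated[1] *
        exp(stats::rnorm(n, 0, spec$rho_T_treated[2])),
      S_T = stats::runif(n, spec$S_T_range[1], spec$S_T_range[2]),
      V0 = stats::rlnorm(n, meanlog, spec$v0_treated_sdlog))
  }
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$spec$n_control, " control + ",
      x$spec$n_treated, " treated subjects, noise sd = ", x$spec$noise_sd,
      ", seed = ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Group-level biomarker panels from a synthetic cohort
#'
#' Evaluates the in silico biomarker panel on each subject's true
#' trajectory at the named epochs and adds additive measurement noise,
#' emulating bulk biomarker measurements reported at the group level.
#'
#' @param cohort a `synthetic_cohort`.
#' @param epochs epoch labels to keep (default all defined).
#' @param noise_sd sd (percentage points) of additive Gaussian noise on
#'   the percentage variables; 0 = noiseless.
#' @param seed RNG seed.
#' @return A data.frame with one row per subject and epoch.
#' @export
generate_biomarker_groups <- function(cohort,
                                      epochs = c("control", "d5", "d21",
                                                 "recurrence"),
                                      noise_sd = 0, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  p_c <- update_params(cohort$spec$params, mu = mu_preset("control"))
  p_t <- update_params(cohort$spec$params, mu = mu_preset("treated"))
  out <- do.call(rbind, lapply(names(cohort$trajectories), function(id) {
    tr <- cohort$trajectories[[id]]
    grp <- cohort$truth$group[cohort$truth$subject_id == id]
    p <- if (grp == "control") p_c else p_t
    p <- update_params(p, rho_T =
                         cohort$truth$true_rho_T[
                           cohort$truth$subject_id == id])
    pan <- epoch_panels(tr, p, subject_id = id)
    pan[pan$epoch %in% epochs, , drop = FALSE]
  }))
  pct_cols <- c("macrophage_pct", "apoptosis_pct", "proliferation_pct",
                "killing_pct", "mg_pct", "mdm_pct")
  if (noise_sd > 0) {
    for (cl in pct_cols) {
      out[[cl]] <- out[[cl]] + stats::rnorm(nrow(out), 0, noise_sd)
    }
    for (cl in setdiff(pct_cols, "killing_pct")) {
      out[[cl]] <- pmin(pmax(out[[cl]], 0), 100)
    }
  }
  rownames(out) <- NULL
  out
}
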