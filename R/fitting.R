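#' Observed longitudinal record for one subject
#'
#' @param subject_id identifier.
#' @param group `"control"` (untreated) or `"treated"` (irradiated).
#' @param times observation days (non-decreasing; the first observation
#'   defines the subject's time origin).
#' @param volumes observed tumor volumes (mm^3, positive).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group = c("control", "treated"),
                           times, volumes) {
  group <- match.arg(group)
  if (length(times) != length(volumes)) {
    stop("'times' and 'volumes' must have equal length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), group = group,
                 times = as.numeric(times), volumes = as.numeric(volumes),
                 first_volume = volumes[1]),
            class = "subject_record")
}

#' Initial population fractions of the tumor volume
#'
#' The first observed volume is distributed over the modeled pools by the
#' volume fractions of tumor cells, anti-tumor microglia and pro-tumor
#' macrophages. In early untreated tumors these are approximately
#' `f_T = 0.96`, `f_A = 0.035` and `f_P = 0.005`.
#'
#' @param f_T,f_A,f_P fractions in `[0, 1]`, summing to 1.
#' @return An object of class `initial_fractions`.
#' @export
initial_fractions <- function(f_T = 0.96, f_A = 0.035, f_P = 0.005) {
  f <- c(f_T = f_T, f_A = f_A, f_P = f_P)
  if (any(f < 0) || any(f > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(f) - 1) > 1e-8) {
    stop("fractions must sum to 1 (got ", sum(f), ")", call. = FALSE)
  }
  structure(as.list(f), class = "initial_fractions")
}

#' Allocate an observed volume to an initial population state
#'
#' Counts are `X0 = f_X * V0 / (v_T * f_T + v_M * f_A + v_M * f_P)` with a
#' single macrophage unit volume `v_M` used for both macrophage pools; the
#' pro-tumor count is split equally between the microglia-derived and
#' MDM-derived subpools. Damaged pools start empty. The reconstructed
#' volume of the returned state equals `V0` exactly.
#'
#' @param V0 observed volume (mm^3, > 0).
#' @param fractions an [initial_fractions()].
#' @param params a [model_params()].
#' @return A [population_state()].
#' @export
allocate_initial_state <- function(V0, fractions, params) {
  if (V0 <= 0) stop("'V0' must be > 0", call. = FALSE)
  denom <- params$v_T * fractions$f_T +
    params$v_M * (fractions$f_A + fractions$f_P)
  if (denom <= 0) stop("unit volumes give a zero denominator", call. = FALSE)
  T0 <- fractions$f_T * V0 / denom
  A0 <- fractions$f_A * V0 / denom
  P0 <- fractions$f_P * V0 / denom
  population_state(T = T0, P1 = P0 / 2, P2 = P0 / 2, A = A0)
}

#' Map relative tumor volume to population fractions
#'
#' Fitted control trajectories reveal how the volume fractions of the three
#' pools evolve as the tumor approaches its maximum size. Pooling all
#' control trajectories, each fraction is regressed by ordinary least
#' squares on the relative volume `V(t) / max V` (per trajectory). The
#' resulting linear maps supply initial fractions for treated subjects,
#' whose first observed volumes are far beyond the early-tumor stage;
#' predictions are clipped to `[0, 1]` and renormalized to sum to 1.
#'
#' @param trajectories list of `population_trajectory` objects for fitted
#'   (or known) control subjects.
#' @return An object of class `proportion_maps` with one OLS line per pool.
#' @export
proportion_regression <- function(trajectories) {
  if (length(trajectories) < 1L) {
    stop("at least one control trajectory is required", call. = FALSE)
  }
  pieces <- lapply(trajectories, function(tr) {
    V <- tr$volume
    p <- tr$params
    data.frame(rel = V / max(V),
               f_T = p$v_T * tr$states[, "T"] / V,
               f_A = p$v_M * tr$states[, "A"] / V,
               f_P = p$v_M * (tr$states[, "P1"] + tr$states[, "P2"]) / V)
  })
  dat <- do.call(rbind, pieces)
  if (stats::sd(dat$rel) < 1e-12) {
    stop("degenerate predictor: relative volume is constant", call. = FALSE)
  }
  fits <- lapply(c("f_T", "f_A", "f_P"), function(nm) {
    stats::coef(stats::lm(dat[[nm]] ~ dat$rel))
  })
  names(fits) <- c("f_T", "f_A", "f_P")
  structure(list(coef = fits, n_points = nrow(dat)),
            class = "proportion_maps")
}

#' Evaluate proportion maps at a relative volume
#'
#' @param maps a `proportion_maps` object.
#' @param rel_volume relative volume in `[0, 1]` (values outside are
#'   evaluated on the line, then clipped).
#' @return An [initial_fractions()] (clipped and renormalized).
#' @export
predict_fractions <- function(maps, rel_volume) {
  stopifnot(inherits(maps, "proportion_maps"))
  f <- vapply(maps$coef, function(cf) cf[[1]] + cf[[2]] * rel_volume,
              numeric(1))
  f <- pmin(pmax(f, 0), 1)
  if (sum(f) <= 0) stop("all predicted fractions are zero", call. = FALSE)
  f <- f / sum(f)
  initial_fractions(f_T = f[["f_T"]], f_A = f[["f_A"]], f_P = f[["f_P"]])
}

# RMSE of model volumes against observations at the record's time points
# (times relative to first observation).
volume_rmse <- function(record, params, sched, fractions,
                        control = solver_control()) {
  t_rel <- record$times - record$times[1]
  init <- allocate_initial_state(record$first_volume, fractions, params)
  horizon <- max(t_rel)
  tr <- simulate_population(init, params, sched, horizon = horizon,
                            output_grid = t_rel, control = control)
  Vhat <- volume_at(tr, t_rel)
  res <- Vhat - record$volumes
  list(rmse = sqrt(mean(res^2)), residuals = res, fitted = Vhat)
}

#' Fit the tumor proliferation rate of an untreated subject
#'
#' Minimizes the root-mean-squared error between model and observed volumes
#' over the single free parameter `rho_T`, by Nelder-Mead simplex search on
#' `log(rho_T)`. The initial state is allocated from the first observed
#' volume. Three fixed multi-start offsets guard against local minima (an
#' engineering addition over a single-start search).
#'
#' @param record a [subject_record()] with `group = "control"` and at least
#'   3 points.
#' @param fixed a [model_params()] holding all fixed parameters; its
#'   `rho_T` seeds the search.
#' @param fractions an [initial_fractions()] for the first observed volume.
#' @param control solver settings (see [solver_control()]).
#' @param maxit maximum simplex iterations per start.
#' @param n_starts number of multi-start offsets (1-3).
#' @return An object of class `twin_fit`: fitted `rho_T`, `rmse`,
#'   residuals, convergence flag.
#' @export
fit_control <- function(record, fixed, fractions = initial_fractions(),
                        control = solver_control(), maxit = 500,
                        n_starts = 3) {
  stopifnot(inherits(record, "subject_record"))
  if (record$group != "control") {
    stop("'record' must belong to the control group", call. = FALSE)
  }
  check_fit_points(record)
  obj <- function(lr) {
    # state blow-up at extreme proposals is penalized, not fatal
    tryCatch(volume_rmse(record, update_params(fixed, rho_T = exp(lr)),
                         NULL, fractions, control)$rmse,
             error = function(e) 1e12)
  }
  starts <- (log(fixed$rho_T) + c(0, -1, 1))[seq_len(n_starts)]
  best <- run_simplex(obj, lapply(starts, identity), maxit)
  rho_T <- exp(best$par)
  conv <- best$converged
  fv <- volume_rmse(record, update_params(fixed, rho_T = rho_T), NULL,
                    fractions, control)
  new_twin_fit(record, rho_T = rho_T, S_T = NA_real_, fv = fv,
               converged = conv, fractions = fractions)
}

#' Fit proliferation rate and radiosensitivity of an irradiated subject
#'
#' Minimizes the RMSE jointly over `(log rho_T, logit S_T)` by Nelder-Mead
#' simplex search (three fixed multi-starts). Initial fractions come from
#' the control-derived proportion maps evaluated at the subject's first
#' volume relative to the reference control's maximum observed volume.
#'
#' @param record a [subject_record()] with `group = "treated"`.
#' @param fixed a [model_params()]; its `rho_T` seeds the search.
#' @param schedule_template a [schedule()] fixing the fraction times
#'   (days relative to the subject's first observation); its `S_T` seeds
#'   the search.
#' @param maps a `proportion_maps` from [proportion_regression()].
#' @param ref_max_volume maximum observed volume of the reference control
#'   subject (mm^3).
#' @param control solver settings.
#' @param maxit maximum simplex iterations per start.
#' @param n_starts number of multi-start offsets (1-3).
#' @return A `twin_fit` with fitted `rho_T`, `S_T`, `rmse`.
#' @export
fit_treated <- function(record, fixed, schedule_template, maps,
                        ref_max_volume, control = solver_control(),
                        maxit = 500, n_starts = 3) {
  stopifnot(inherits(record, "subject_record"))
  if (record$group != "treated") {
    stop("'record' must belong to the treated group", call. = FALSE)
  }
  check_fit_points(record)
  fractions <- predict_fractions(maps, record$first_volume / ref_max_volume)
  template <- schedule_template
  obj <- function(th) {
    p <- update_params(fixed, rho_T = exp(th[1]))
    sch <- schedule(ir_times = template$ir_times,
                    S_T = stats::plogis(th[2]),
                    therapies = template$therapies)
    tryCatch(volume_rmse(record, p, sch, fractions, control)$rmse,
             error = function(e) 1e12)
  }
  s0 <- c(log(fixed$rho_T), stats::qlogis(min(max(template$S_T, 1e-3),
                                              1 - 1e-3)))
  starts <- list(s0, s0 + c(-1, 1), s0 + c(1, -1))[seq_len(n_starts)]
  best <- run_simplex(obj, starts, maxit)
  rho_T <- exp(best$par[1])
  S_T <- stats::plogis(best$par[2])
  conv <- best$converged
  sch <- schedule(ir_times = template$ir_times, S_T = S_T,
                  therapies = template$therapies)
  fv <- volume_rmse(record, update_params(fixed, rho_T = rho_T), sch,
                    fractions, control)
  new_twin_fit(record, rho_T = rho_T, S_T = S_T, fv = fv, converged = conv,
               fractions = fractions, sched = sch)
}

# Multi-start Nelder-Mead with a restart from the incumbent: a simplex that
# has collapsed along one direction is rebuilt around the best point, the
# standard remedy for premature convergence of the downhill simplex.
run_simplex <- function(obj, starts, maxit) {
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- suppressWarnings(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10)))
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  for (r in 1:2) {
    o <- suppressWarnings(
      stats::optim(best$par, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-12)))
    if (o$value < best$value) best <- o else break
  }
  best$converged <- conv
  best
}

check_fit_points <- function(record) {
  if (length(record$times) < 3L) {
    stop("at least 3 observation points are required to fit subject '",
         record$subject_id, "'", call. = FALSE)
  }
}

new_twin_fit <- function(record, rho_T, S_T, fv, converged, fractions,
                         sched = NULL) {
  structure(list(subject_id = record$subject_id, group = record$group,
                 rho_T = rho_T, S_T = S_T, rmse = fv$rmse,
                 residuals = fv$residuals, fitted_volumes = fv$fitted,
                 n_points = length(record$times), converged = converged,
                 fractions = fractions, schedule = sched, record = record),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat("<twin_fit> subject ", x$subject_id, " (", x$group, "): rho_T = ",
      signif(x$rho_T, 5),
      if (!is.na(x$S_T)) paste0(", S_T = ", signif(x$S_T, 4)) else "",
      ", RMSE = ", signif(x$rmse, 4), " mm^3 over ", x$n_points,
      " points\n", sep = "")
  invisible(x)
}

#' Fit a whole cohort
#'
#' Fits every control subject first (single free parameter `rho_T`,
#' control-group killing-rate preset), simulates the fitted control
#' trajectories, builds the proportion regressions from them, and then fits
#' every treated subject (`rho_T` and `S_T`, treated-group preset). The
#' reference control for a treated subject's relative volume is the control
#' with the largest observed volume.
#'
#' @param records list of [subject_record()]s (both groups).
#' @param fixed a [model_params()] shared by all subjects; the group-keyed
#'   killing-rate preset is applied per group via [mu_preset()].
#' @param schedule_template a [schedule()] with the fraction times for
#'   treated subjects.
#' @param fractions an [initial_fractions()] for control subjects.
#' @param control solver settings.
#' @param n_starts number of multi-start offsets per subject (1-3).
#' @return A list of class `cohort_fit` with `fits` (list of `twin_fit`),
#'   `maps`, `ref_max_volume` and a `report` data.frame (subject_id, group,
#'   rho_T, S_T, rmse, n_points, converged).
#' @export
fit_cohort <- function(records, fixed = model_params(),
                       schedule_template = ir_course(start_day = 1),
                       fractions = initial_fractions(),
                       control = solver_control(), n_starts = 3) {
  groups <- vapply(records, function(r) r$group, character(1))
  controls <- records[groups == "control"]
  treated <- records[groups == "treated"]
  fixed_c <- update_params(fixed, mu = mu_preset("control"))
  fixed_t <- update_params(fixed, mu = mu_preset("treated"))

  control_fits <- lapply(controls, fit_control, fixed = fixed_c,
                         fractions = fractions, control = control,
                         n_starts = n_starts)
  control_trajs <- lapply(control_fits, function(f) {
    t_rel <- f$record$times - f$record$times[1]
    p <- update_params(fixed_c, rho_T = f$rho_T)
    init <- allocate_initial_state(f$record$first_volume, f$fractions, p)
    simulate_population(init, p, NULL, horizon = max(t_rel),
                        output_grid = seq(0, max(t_rel), length.out = 101L),
                        control = control)
  })

  maps <- NULL
  treated_fits <- list()
  ref_max <- NA_real_
  if (length(treated)) {
    if (length(controls) < 2L) {
      stop("fitting treated subjects requires >= 2 control subjects",
           call. = FALSE)
    }
    maps <- proportion_regression(control_trajs)
    ref_max <- max(vapply(controls, function(r) max(r$volumes), numeric(1)))
    treated_fits <- lapply(treated, fit_treated, fixed = fixed_t,
                           schedule_template = schedule_template,
                           maps = maps, ref_max_volume = ref_max,
                           control = control, n_starts = n_starts)
  }

  fits <- c(control_fits, treated_fits)
  report <- do.call(rbind, lapply(fits, function(f) {
    data.frame(subject_id = f$subject_id, group = f$group, rho_T = f$rho_T,
               S_T = f$S_T, rmse = f$rmse, n_points = f$n_points,
               converged = f$converged)
  }))
  structure(list(fits = fits, maps = maps, ref_max_volume = ref_max,
                 control_trajectories = control_trajs, report = report,
                 fixed = fixed, schedule_template = schedule_template),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat("<cohort_fit> ", sum(x$report$group == "control"), " control + ",
      sum(x$report$group == "treated"), " treated subjects\n", sep = "")
  print(x$report, row.names = FALSE)
  invisible(x)
}
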