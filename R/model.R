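#' Right-hand side of the tumor-macrophage ODE system
#'
#' The model couples tumor cells `T`, pro-tumor macrophages `P = P1 + P2`
#' and anti-tumor macrophages `A` through a cooperative Gompertzian core:
#' each population's proliferation is proportional to the partner population
#' and to `ln(K / V)`, so growth stalls at the carrying capacity. Anti-tumor
#' macrophages kill tumor cells at rate `mu`; tumor cells convert microglia
#' to the pro-tumor phenotype through a saturating term and recruit MDMs
#' from the vasculature at rate `phi * T`; tumor expansion recruits fresh
#' microglia (`xi` times the tumor growth rate); macrophages decay with
#' lifespan `tau_M`. Damaged pools created by irradiation decay
#' exponentially with their clearance times and, once irradiation has
#' occurred, feed an inflammation flux `phi_D * (TD + MD)` into the
#' anti-tumor pool.
#'
#' The pro-tumor derivative is distributed over the two provenance subpools
#' so that their sum obeys the pooled equation exactly: the conversion term
#' accrues to `P1` (microglia-derived), the influx to `P2` (MDM-derived),
#' and proliferation and decay act pro rata on each subpool.
#'
#' @param t time (days); the autonomous system ignores it except through
#'   modifiers resolved upstream.
#' @param state a [population_state()] or named numeric vector.
#' @param params a [model_params()].
#' @param modifiers instantaneous effective modifiers (see
#'   [active_modifiers()]).
#' @param ir_active logical; `TRUE` once at least one radiation fraction has
#'   been delivered (activates the inflammation flux).
#' @return Named numeric vector of derivatives (cells per day) for
#'   `T, P1, P2, A, TD, MD`.
#' @export
population_rhs <- function(t, state, params,
                           modifiers = list(mu_multiplier = 1,
                                            influx_attenuation = 1,
                                            lambda_override = NULL),
                           ir_active = FALSE) {
  s <- as_state_vector(state)
  d <- rhs_core(s, params,
                mu_eff = params$mu * modifiers$mu_multiplier,
                lam_eff = if (is.null(modifiers$lambda_override)) params$lam
                          else modifiers$lambda_override,
                ir_active = ir_active)
  if (any(!is.finite(d))) {
    stop("non-finite derivative in compartment(s): ",
         paste(state_names[!is.finite(d)], collapse = ", "),
         " (volume = ", volume(s, params), " mm^3)", call. = FALSE)
  }
  names(d) <- state_names
  d
}

# Fast unchecked core shared with the integrator. `s` is a numeric vector in
# canonical order T, P1, P2, A, TD, MD.
rhs_core <- function(s, params, mu_eff, lam_eff, ir_active) {
  T <- s[[1L]]; P1 <- s[[2L]]; P2 <- s[[3L]]; A <- s[[4L]]
  TD <- s[[5L]]; MD <- s[[6L]]
  P <- P1 + P2
  V <- params$v_T * (T + TD) + params$v_M * (P + A + MD)
  lnKV <- if (V > 0) log(params$K / V) else 0
  conv <- if (params$conversion_form == "saturated") {
    lam_eff * A * T * params$K_lam / (params$K_lam + T)
  } else {
    lam_eff * A * T / (params$K_lam + T)
  }
  dT <- params$rho_T * T * P * lnKV - mu_eff * T * A
  recruit <- if (params$clamp_recruitment) max(dT, 0) else dT
  inv_tau <- 1 / params$tau_M
  dP1 <- params$rho_P * P1 * T * lnKV + conv - P1 * inv_tau
  dP2 <- params$rho_P * P2 * T * lnKV + params$phi * T - P2 * inv_tau
  dA <- params$rho_A * A * T * lnKV - conv + params$xi * recruit -
    A * inv_tau
  if (ir_active) dA <- dA + params$phi_D * (TD + MD)
  c(dT, dP1, dP2, dA, -TD / params$tau_TD, -MD / params$tau_MD)
}

#' Solver settings
#'
#' Adaptive Runge-Kutta 4(5) with relative tolerance `1e-10` and absolute
#' tolerance `1e-6` cells by default. The cooperative feedback makes the
#' growth ramp locally very fast (per-capita rates of tens per day), which
#' amplifies integration error; the tight default keeps trajectories
#' accurate to well below 0.1% through the ramp, and the compiled
#' right-hand side keeps this cheap.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance (cells).
#' @param method a [deSolve::rkMethod()] name; default `"ode45"`.
#' @return A list of solver settings.
#' @export
solver_control <- function(rtol = 1e-10, atol = 1e-6, method = "ode45") {
  list(rtol = rtol, atol = atol, method = method)
}

#' Simulate the model under a treatment schedule
#'
#' Integrates the system piecewise between consecutive events. At each
#' radiation fraction the impulsive map of [apply_ir_fraction()] is applied
#' and integration restarts from the mapped state; therapy windows toggle
#' the effective modifiers at their boundaries. The inflammation flux is
#' active from the first fraction onward.
#'
#' @param initial a [population_state()].
#' @param params a [model_params()].
#' @param sched a [schedule()], or `NULL` for untreated growth.
#' @param horizon simulation end time (days, > 0); simulation runs over
#'   `[0, horizon]`.
#' @param output_grid times (days) at which the trajectory is reported;
#'   defaults to 401 evenly spaced points over the horizon. Event times are
#'   always included.
#' @param control a [solver_control()].
#' @return An object of class `population_trajectory`: list with `times`,
#'   `states` (matrix, one row per time), `volume`, `event_log`
#'   (data.frame of applied impulses and window boundaries with pre/post
#'   snapshots), `params` (as at t = 0), `params_final` (with escalated
#'   `phi`), `schedule`, `horizon`.
#' @export
simulate_population <- function(initial, params, sched = NULL, horizon,
                                output_grid = NULL,
                                control = solver_control()) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(sched)) sched <- schedule()
  stopifnot(inherits(sched, "schedule"))
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("'horizon' must be > 0", call. = FALSE)
  }
  if (is.null(output_grid)) {
    output_grid <- seq(0, horizon, length.out = 401L)
  }
  output_grid <- sort(unique(output_grid))
  if (min(output_grid) < 0 || max(output_grid) > horizon) {
    stop("'output_grid' must lie within [0, horizon]", call. = FALSE)
  }

  ir_times <- sched$ir_times[sched$ir_times >= 0 & sched$ir_times <= horizon]
  if (length(sched$ir_times) && length(ir_times) < length(sched$ir_times)) {
    warning("radiation fractions outside [0, horizon] are ignored")
  }
  win_bounds <- unlist(lapply(sched$therapies, function(th) th$window))
  win_bounds <- win_bounds[is.finite(win_bounds) & win_bounds > 0 &
                             win_bounds < horizon]
  breaks <- sort(unique(c(0, ir_times, win_bounds, horizon)))

  y <- as_state_vector(initial)
  p <- params
  ir_active <- FALSE
  method <- deSolve::rkMethod(control$method)

  times_out <- numeric(0)
  rows <- list()
  log_rows <- list()

  record <- function(tt, ymat) {
    times_out <<- c(times_out, tt)
    rows[[length(rows) + 1L]] <<- ymat
  }

  # impulse at t = 0, if scheduled
  if (length(ir_times) && ir_times[1] == 0) {
    mod0 <- active_modifiers(sched$therapies, 0, p)
    pre <- y
    imp <- apply_ir_fraction(y, p, sched$S_T, mod0)
    y <- as_state_vector(imp$state)
    p <- imp$params
    ir_active <- TRUE
    log_rows[[length(log_rows) + 1L]] <- impulse_log_row(0, pre, y, imp, p)
    ir_times <- ir_times[-1]
  }

  seg_start <- breaks[-length(breaks)]
  seg_end <- breaks[-1]
  for (k in seq_along(seg_start)) {
    a <- seg_start[k]; b <- seg_end[k]
    mod <- active_modifiers(sched$therapies, a, p)
    mu_eff <- p$mu * mod$mu_multiplier
    lam_eff <- if (is.null(mod$lambda_override)) p$lam else mod$lambda_override
    seg_times <- sort(unique(c(a, output_grid[output_grid > a &
                                                output_grid < b], b)))
    # parameter vector for the compiled right-hand side; the volume guard
    # freezes runaway proposals far above K (unreachable legitimately,
    # since growth reverses at V = K) so they cannot exhaust step budgets
    pv <- c(p$rho_T, p$rho_P, p$rho_A, mu_eff, lam_eff, p$K_lam, p$phi,
            p$xi, p$tau_M, p$K, p$v_T, p$v_M, p$tau_TD, p$tau_MD, p$phi_D,
            if (p$conversion_form == "saturated") 0 else 1,
            as.numeric(p$clamp_recruitment), as.numeric(ir_active),
            3 * p$K)
    sol <- deSolve::ode(y = y, times = seg_times, func = "gtw_derivs",
                        parms = pv, dllname = "gliomatwin",
                        initfunc = "gtw_initmod",
                        method = method, rtol = control$rtol,
                        atol = control$atol)
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[, -1]))) {
      stop("integration failed in [", a, ", ", b, "]; last valid time ",
           max(sol[is.finite(rowSums(sol[, -1, drop = FALSE])), 1]),
           call. = FALSE)
    }
    ymat <- unname(sol[, 1 + seq_len(6), drop = FALSE])
    # tiny negative undershoots within absolute tolerance are numerical
    ymat[ymat < 0 & ymat > -10 * control$atol] <- 0
    record(sol[, 1], ymat)
    y <- ymat[nrow(ymat), ]
    names(y) <- state_names

    if (b %in% ir_times) {
      modb <- active_modifiers(sched$therapies, b, p)
      pre <- y
      imp <- apply_ir_fraction(y, p, sched$S_T, modb)
      y <- as_state_vector(imp$state)
      p <- imp$params
      ir_active <- TRUE
      log_rows[[length(log_rows) + 1L]] <- impulse_log_row(b, pre, y, imp, p)
      # replace the recorded pre-impulse row at b by the post-impulse state
      last <- length(rows)
      rows[[last]][nrow(rows[[last]]), ] <- y
    } else if (b < horizon) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(time = b, type = "window_boundary", escalation = NA_real_,
                   phi_after = p$phi, volume_pre = volume(y, p),
                   volume_post = volume(y, p))
    }
  }

  states <- do.call(rbind, rows)
  keep <- !duplicated(times_out)
  times_all <- times_out[keep]
  states <- states[keep, , drop = FALSE]
  colnames(states) <- state_names
  vol <- params$v_T * (states[, "T"] + states[, "TD"]) +
    params$v_M * (states[, "P1"] + states[, "P2"] + states[, "A"] +
                    states[, "MD"])
  event_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(time = numeric(0), type = character(0),
               escalation = numeric(0), phi_after = numeric(0),
               volume_pre = numeric(0), volume_post = numeric(0))
  structure(list(times = times_all, states = states, volume = vol,
                 event_log = event_log, params = params, params_final = p,
                 schedule = sched, horizon = horizon),
            class = "population_trajectory")
}

impulse_log_row <- function(tt, pre, post, imp, p) {
  data.frame(time = tt, type = "ir_fraction", escalation = imp$escalation,
             phi_after = p$phi,
             volume_pre = volume(pre, p), volume_post = volume(post, p))
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat("<population_trajectory> ", length(x$times), " time points over [0, ",
      x$horizon, "] d; ", sum(x$event_log$type == "ir_fraction"),
      " IR fraction(s)\n", sep = "")
  cat("  final volume: ", signif(x$volume[length(x$volume)], 5), " mm^3\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.population_trajectory <- function(x, ...) {
  data.frame(time_d = x$times,
             T = x$states[, "T"], P1 = x$states[, "P1"],
             P2 = x$states[, "P2"], A = x$states[, "A"],
             TD = x$states[, "TD"], MD = x$states[, "MD"],
             volume_mm3 = x$volume)
}

#' Interpolate the state of a trajectory at arbitrary times
#'
#' Linear interpolation per compartment on the stored grid.
#'
#' @param traj a `population_trajectory`.
#' @param t times (days) within the trajectory span.
#' @return A matrix with one row per time and the six compartment columns.
#' @export
state_at <- function(traj, t) {
  if (any(t < traj$times[1] - 1e-9 | t > traj$times[length(traj$times)] + 1e-9)) {
    stop("time outside trajectory span", call. = FALSE)
  }
  out <- vapply(state_names, function(nm) {
    stats::approx(traj$times, traj$states[, nm], xout = t, rule = 2)$y
  }, numeric(length(t)))
  if (length(t) == 1L) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL, state_names))
  out
}

#' Interpolate trajectory volume at arbitrary times
#'
#' @param traj a `population_trajectory`.
#' @param t times (days).
#' @return Volumes (mm^3).
#' @export
volume_at <- function(traj, t) {
  stats::approx(traj$times, traj$volume, xout = t, rule = 2)$y
}
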