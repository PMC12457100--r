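#' In silico biomarker panel at a time point
#'
#' Computes count-based analogues of the experimental immunostaining and
#' flow-cytometry panel from a simulated trajectory:
#'
#' * `macrophage_pct` (Iba1-like): live and damaged macrophages as a
#'   percentage of all cells, `100 * (P1 + P2 + A + MD) / total`.
#' * `apoptosis_pct` (CC3-like): damaged pools as a percentage of all
#'   cells, `100 * (TD + MD) / total`.
#' * `proliferation_pct` (Ki67-like): the instantaneous per-cell tumor
#'   growth rate `rho_T * P * ln(K / V)` converted to a labeled fraction by
#'   the cycle-time constant `tau_cycle` (default 1 day), clipped to
#'   `[0, 100]`.
#' * `killing_pct`: percentage of tumor cells eliminated per day by
#'   anti-tumor macrophages, `100 * mu_eff * A`.
#' * `mg_pct` / `mdm_pct` (CD49d-/CD49d+-like): microglia-derived
#'   (`A + P1`) versus MDM-derived (`P2`) share of the live macrophage
#'   pool; they sum to 100.
#'
#' These formulas are this package's definitions of the panel; they are
#' count-based analogues chosen for interpretability, not literature-fixed
#' quantities.
#'
#' @param traj a `population_trajectory`.
#' @param t day within the trajectory span.
#' @param params a [model_params()].
#' @param modifiers instantaneous effective modifiers (see
#'   [active_modifiers()]); only `mu_multiplier` is consulted.
#' @param tau_cycle cycle-time constant (days) for the Ki67 analogue.
#' @param epoch optional epoch label carried through.
#' @param subject_id optional subject identifier carried through.
#' @return A one-row data.frame of class `biomarker_panel`.
#' @export
biomarker_panel <- function(traj, t, params,
                            modifiers = list(mu_multiplier = 1),
                            tau_cycle = 1, epoch = NA_character_,
                            subject_id = NA_character_) {
  if (length(t) != 1L || t < traj$times[1] - 1e-9 ||
      t > traj$times[length(traj$times)] + 1e-9) {
    stop("'t' must be a single day within the trajectory span", call. = FALSE)
  }
  s <- drop(state_at(traj, t))
  total <- sum(s)
  macro <- s[["P1"]] + s[["P2"]] + s[["A"]] + s[["MD"]]
  live_m <- s[["P1"]] + s[["P2"]] + s[["A"]]
  P <- s[["P1"]] + s[["P2"]]
  V <- volume(s, params)
  lnKV <- if (V > 0) log(params$K / V) else 0
  prolif <- 100 * params$rho_T * P * lnKV * tau_cycle
  out <- data.frame(
    subject_id = subject_id, epoch = epoch, time_d = t,
    macrophage_pct = if (total > 0) 100 * macro / total else 0,
    apoptosis_pct = if (total > 0) 100 * (s[["TD"]] + s[["MD"]]) / total
                    else 0,
    proliferation_pct = min(max(prolif, 0), 100),
    killing_pct = killing_pct(s, params, modifiers),
    mg_pct = if (live_m > 0) 100 * (s[["A"]] + s[["P1"]]) / live_m
             else NA_real_,
    mdm_pct = if (live_m > 0) 100 * s[["P2"]] / live_m else NA_real_)
  class(out) <- c("biomarker_panel", "data.frame")
  out
}

#' Tumor-cell killing rate by anti-tumor macrophages
#'
#' The per-day percentage of tumor cells eliminated through the kill term,
#' `100 * mu_eff * A`.
#'
#' @param state a [population_state()] or named vector.
#' @param params a [model_params()].
#' @param modifiers effective modifiers; `mu_multiplier` scales `mu`.
#' @return Percent of tumor cells killed per day.
#' @export
killing_pct <- function(state, params,
                        modifiers = list(mu_multiplier = 1)) {
  s <- as_state_vector(state)
  mult <- modifiers$mu_multiplier
  if (is.null(mult)) mult <- 1
  100 * params$mu * mult * s[["A"]]
}

#' Time-averaged tumor-cell killing over a trajectory
#'
#' Trapezoidal time-average of [killing_pct()] over the trajectory span.
#'
#' @param traj a `population_trajectory`.
#' @param params a [model_params()].
#' @param modifiers effective modifiers; `mu_multiplier` scales `mu`.
#' @return Time-averaged killing (percent per day).
#' @export
time_averaged_killing <- function(traj, params,
                                  modifiers = list(mu_multiplier = 1)) {
  tt <- traj$times
  if (length(tt) < 2L || diff(range(tt)) <= 0) {
    stop("trajectory span is empty", call. = FALSE)
  }
  mult <- modifiers$mu_multiplier
  if (is.null(mult)) mult <- 1
  k <- 100 * params$mu * mult * traj$states[, "A"]
  sum(diff(tt) * (k[-1] + k[-length(k)]) / 2) / diff(range(tt))
}

#' Epoch times for the biomarker comparisons
#'
#' Named epochs mirror the experimental sampling design: `control` is the
#' first observation, `d5` the end of the irradiation course, `d21` is 21
#' days after irradiation started, and `recurrence` the first post-course
#' time at which the volume re-attains its value just before the first
#' fraction.
#'
#' @param traj a `population_trajectory` (treated; for untreated
#'   trajectories only `control` is defined).
#' @return Named numeric vector of epoch days (NA when undefined or not
#'   reached within the horizon).
#' @export
epoch_times <- function(traj) {
  t0 <- traj$times[1]
  ir <- traj$event_log$time[traj$event_log$type == "ir_fraction"]
  if (!length(ir)) {
    return(c(control = t0, d5 = NA_real_, d21 = NA_real_,
             recurrence = NA_real_))
  }
  course_end <- max(ir)
  d21 <- min(ir) + 21
  if (d21 > traj$horizon) d21 <- NA_real_
  pre_ir <- traj$event_log$volume_pre[traj$event_log$type == "ir_fraction"][1]
  after <- traj$times > course_end
  rec <- NA_real_
  if (any(after)) {
    idx <- which(after & traj$volume >= pre_ir)
    if (length(idx)) rec <- traj$times[min(idx)]
  }
  c(control = t0, d5 = course_end, d21 = d21, recurrence = rec)
}

#' Biomarker panels at the named epochs
#'
#' @param traj a `population_trajectory`.
#' @param params a [model_params()].
#' @param subject_id identifier carried into the rows.
#' @param tau_cycle cycle-time constant for the Ki67 analogue.
#' @return A data.frame with one row per defined epoch.
#' @export
epoch_panels <- function(traj, params, subject_id = NA_character_,
                         tau_cycle = 1) {
  ep <- epoch_times(traj)
  ep <- ep[!is.na(ep)]
  out <- do.call(rbind, lapply(names(ep), function(nm) {
    biomarker_panel(traj, ep[[nm]], params, epoch = nm,
                    subject_id = subject_id, tau_cycle = tau_cycle)
  }))
  out
}
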