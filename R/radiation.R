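#' Irradiation schedule and therapy windows
#'
#' A schedule holds the times of the discrete radiation fractions, the
#' per-subject tumor survival fraction `S_T`, and any therapy windows. The
#' standard course is 5 daily fractions; protracted schedules vary only the
#' inter-fraction interval.
#'
#' @param ir_times fraction times in days (strictly increasing), or `NULL`
#'   for no irradiation.
#' @param S_T tumor-cell survival fraction per fraction, in `(0, 1]`.
#' @param therapies list of [therapy_modifiers()] windows.
#' @return An object of class `schedule`.
#' @export
schedule <- function(ir_times = NULL, S_T = 1, therapies = list()) {
  if (!is.null(ir_times)) {
    ir_times <- as.numeric(ir_times)
    if (length(ir_times) && any(diff(ir_times) <= 0)) {
      stop("'ir_times' must be strictly increasing", call. = FALSE)
    }
  } else {
    ir_times <- numeric(0)
  }
  if (S_T <= 0 || S_T > 1) stop("'S_T' must lie in (0, 1]", call. = FALSE)
  if (inherits(therapies, "therapy_modifiers")) therapies <- list(therapies)
  stopifnot(all(vapply(therapies, inherits, logical(1), "therapy_modifiers")))
  structure(list(ir_times = ir_times, S_T = S_T, therapies = therapies),
            class = "schedule")
}

#' Standard fractionated course
#'
#' @param start_day day of the first fraction.
#' @param n_fractions number of fractions (default 5).
#' @param interval_days days between consecutive fractions (1 = daily;
#'   larger values give a protracted course).
#' @param S_T tumor survival fraction per fraction.
#' @param therapies list of [therapy_modifiers()].
#' @return A [schedule()].
#' @export
ir_course <- function(start_day = 1, n_fractions = 5, interval_days = 1,
                      S_T = 0.4, therapies = list()) {
  schedule(ir_times = start_day + interval_days * seq(0, n_fractions - 1),
           S_T = S_T, therapies = therapies)
}

#' Apply one radiation fraction as an impulsive map
#'
#' A fraction instantaneously transfers `(1 - S_T)` of the tumor cells to
#' the damaged-tumor pool and `(1 - S_M)` of all live macrophages (both
#' pro-tumor subpools and the anti-tumor pool, damaged jointly) to the
#' damaged-macrophage pool. Total cell count is conserved at the instant.
#' The MDM influx coefficient `phi` escalates by `1/S_T` per fraction
#' (compounding), attenuated to `1 + a * (1/S_T - 1)` when an active therapy
#' supplies an attenuation `a < 1`.
#'
#' @param state a [population_state()].
#' @param params a [model_params()] (supplies `S_M` and the current `phi`).
#' @param S_T tumor survival fraction for this fraction, in `(0, 1]`.
#' @param modifiers instantaneous effective modifiers as returned by
#'   [active_modifiers()]; only `influx_attenuation` is consulted.
#' @return A list with the post-impulse `state` and `params` (updated
#'   `phi`).
#' @export
apply_ir_fraction <- function(state, params, S_T,
                              modifiers = list(influx_attenuation = 1)) {
  if (!is.numeric(S_T) || length(S_T) != 1L || S_T <= 0 || S_T > 1) {
    stop("'S_T' must lie in (0, 1]", call. = FALSE)
  }
  S_M <- params$S_M
  s <- as_state_vector(state)
  live_m <- s[["P1"]] + s[["P2"]] + s[["A"]]
  post <- c(T = S_T * s[["T"]],
            P1 = S_M * s[["P1"]],
            P2 = S_M * s[["P2"]],
            A = S_M * s[["A"]],
            TD = s[["TD"]] + (1 - S_T) * s[["T"]],
            MD = s[["MD"]] + (1 - S_M) * live_m)
  a <- modifiers$influx_attenuation
  if (is.null(a)) a <- 1
  escalation <- 1 + a * (1 / S_T - 1)
  params$phi <- params$phi * escalation
  list(state = structure(post, class = "population_state"),
       params = params, escalation = escalation)
}
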