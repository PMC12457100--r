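#' Therapy modifiers
#'
#' Myeloid-targeted interventions act on the model as parameter modifiers
#' with activation windows: a multiplier on the macrophage killing rate
#' `mu`, an attenuation of the IR-induced escalation of the MDM influx
#' coefficient `phi`, and an optional override of the conversion coefficient
#' `lam` (a negative override reverses the polarization of the
#' microglia-to-pro-tumor transition through the same saturating term).
#' Neutral modifiers reproduce the unmodified model exactly.
#'
#' Windows are half-open, active on `[start, end)`.
#'
#' @param mu_multiplier factor applied to `mu` (>= 0); 1 is neutral.
#' @param influx_attenuation fraction `a` in `[0, 1]` of the IR-induced
#'   `phi` escalation allowed through: each fraction inside the window
#'   escalates `phi` by `1 + a * (1/S_T - 1)` instead of `1/S_T`. `a = 1` is
#'   neutral, `a = 0` fully blocks the IR-induced increase (the baseline
#'   `phi * T` influx continues).
#' @param lambda_override optional signed coefficient replacing `lam` inside
#'   the window; `NULL` is neutral.
#' @param window numeric length-2 `(start, end)` in days; `end = Inf` means
#'   open-ended.
#' @param id short identifier used in event logs.
#' @return An object of class `therapy_modifiers`.
#' @seealso [anti_cd47()], [alpha_cd49d()], [csf1r_inhibitor()]
#' @export
therapy_modifiers <- function(mu_multiplier = 1,
                              influx_attenuation = 1,
                              lambda_override = NULL,
                              window = c(0, Inf),
                              id = "custom") {
  if (!is.numeric(mu_multiplier) || mu_multiplier < 0) {
    stop("'mu_multiplier' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(influx_attenuation) || influx_attenuation < 0 ||
      influx_attenuation > 1) {
    stop("'influx_attenuation' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(lambda_override) &&
      (!is.numeric(lambda_override) || length(lambda_override) != 1L ||
       !is.finite(lambda_override))) {
    stop("'lambda_override' must be NULL or a single finite number",
         call. = FALSE)
  }
  if (length(window) != 2L || window[1] > window[2]) {
    stop("'window' must be (start, end) with start <= end", call. = FALSE)
  }
  structure(list(mu_multiplier = mu_multiplier,
                 influx_attenuation = influx_attenuation,
                 lambda_override = lambda_override,
                 window = as.numeric(window),
                 id = id),
            class = "therapy_modifiers")
}

#' Anti-CD47 phagocytosis boost
#'
#' Blocking the CD47-SIRPalpha "don't eat me" axis enhances macrophage
#' phagocytosis of tumor cells; modelled as a multiplier on the killing rate
#' `mu`. The default multiplier of 3 is a deliberately conservative reading
#' of the ~5-fold increase reported in xenograft phagocytosis assays. The
#' default window runs from its start day to the end of the simulation
#' (a sustained phenotype change).
#'
#' @param multiplier factor (> 0) applied to `mu` inside the window.
#' @param window activation window `(start, end)` in days.
#' @return A `therapy_modifiers` object.
#' @export
anti_cd47 <- function(multiplier = 3, window = c(0, Inf)) {
  if (multiplier <= 0) stop("'multiplier' must be > 0", call. = FALSE)
  therapy_modifiers(mu_multiplier = multiplier, window = window,
                    id = "anti_cd47")
}

#' alpha-CD49d blockade of IR-induced MDM influx
#'
#' Neutralizing integrin alpha-4 limits monocyte trafficking into the brain;
#' modelled as an attenuation of the IR-induced escalation of `phi`. The
#' default `attenuation = 0` is the strongest reading (full blockade of the
#' escalation); baseline influx `phi * T` is never affected.
#'
#' @param attenuation `a` in `[0, 1]`; fraction of the escalation allowed
#'   through.
#' @param window activation window `(start, end)` in days.
#' @return A `therapy_modifiers` object.
#' @export
alpha_cd49d <- function(attenuation = 0, window = c(0, Inf)) {
  therapy_modifiers(influx_attenuation = attenuation, window = window,
                    id = "alpha_cd49d")
}

#' CSF-1R inhibition
#'
#' Blockade of the CSF-1 receptor has three combined effects inside its
#' window: (i) enhanced phagocytic activity (multiplier on `mu`; the default
#' of 3 mirrors the anti-CD47 default and is an assumption, no number being
#' established for this agent), (ii) blockade of the IR-induced `phi`
#' escalation, and (iii) reversal of macrophage polarization, modelled by
#' overriding `lam` with a negative value so the saturating conversion term
#' moves cells from the pro-tumor to the anti-tumor pool. The default
#' override is `-lam` (equal magnitude, opposite sign). The standard course
#' is 12 days; an open-ended window models continuous administration.
#'
#' @param mu_multiplier factor on `mu` inside the window.
#' @param attenuation `a` in `[0, 1]` for the IR escalation of `phi`.
#' @param lambda_override replacement for `lam`; `NULL` means "negate the
#'   parameter set's `lam`" and is resolved at simulation time.
#' @param window activation window, default `(start, start + 12)` days.
#' @param start start day used when `window` is not given.
#' @return A `therapy_modifiers` object.
#' @export
csf1r_inhibitor <- function(mu_multiplier = 3, attenuation = 0,
                            lambda_override = NULL,
                            window = NULL, start = 0) {
  if (is.null(window)) window <- c(start, start + 12)
  m <- therapy_modifiers(mu_multiplier = mu_multiplier,
                         influx_attenuation = attenuation,
                         lambda_override = lambda_override,
                         window = window, id = "csf1r")
  m$negate_lambda <- is.null(lambda_override)
  m
}

neutral_modifiers <- function() {
  therapy_modifiers(id = "neutral")
}

#' Combine the modifiers active at a time point
#'
#' Multiplier and attenuation effects compose multiplicatively (they touch
#' disjoint parameters, so composition is commutative); at most one active
#' therapy may override `lam`.
#'
#' @param therapies list of `therapy_modifiers`.
#' @param t time (days).
#' @param params `model_params`, used to resolve a deferred `-lam` override.
#' @return A list with `mu_multiplier`, `influx_attenuation`,
#'   `lambda_override` (or `NULL`) describing the instantaneous effective
#'   modifiers.
#' @export
active_modifiers <- function(therapies, t, params = NULL) {
  eff <- list(mu_multiplier = 1, influx_attenuation = 1,
              lambda_override = NULL)
  for (th in therapies) {
    w <- th$window
    if (t < w[1] || t >= w[2]) next
    eff$mu_multiplier <- eff$mu_multiplier * th$mu_multiplier
    eff$influx_attenuation <- eff$influx_attenuation * th$influx_attenuation
    ov <- th$lambda_override
    if (is.null(ov) && isTRUE(th$negate_lambda)) {
      ov <- if (is.null(params)) NA_real_ else -params$lam
    }
    if (!is.null(ov)) {
      if (!is.null(eff$lambda_override)) {
        stop("two active therapies both override 'lam' at t = ", t,
             call. = FALSE)
      }
      eff$lambda_override <- ov
    }
  }
  eff
}
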