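#' Model parameters for the tumor-macrophage system
#'
#' Bundles all rate constants of the glioma growth model: Gompertzian
#' proliferation coefficients for tumor cells and both macrophage phenotypes,
#' the macrophage-mediated tumor-killing rate, the saturating
#' microglia-to-pro-tumor conversion, the monocyte-derived macrophage (MDM)
#' influx coefficient, microglia recruitment coupling, macrophage lifespan,
#' carrying capacity, unit cell volumes, damaged-pool clearance times, the
#' macrophage survival fraction per radiation fraction, and the inflammation
#' flux coefficient.
#'
#' The tumor proliferation coefficient `rho_T` is the per-subject free
#' parameter of the fitting procedure. `phi` is mutable state across
#' irradiation events: each fraction escalates it (see
#' [apply_ir_fraction()]).
#'
#' @param rho_T tumor proliferation coefficient (per day per pro-tumor
#'   macrophage), the per-subject free parameter.
#' @param rho_P pro-tumor macrophage proliferation coefficient (per day per
#'   tumor cell).
#' @param rho_A anti-tumor macrophage proliferation coefficient (per day per
#'   tumor cell).
#' @param mu tumor-killing rate by anti-tumor macrophages (per day per cell).
#'   Two calibrated presets exist, one per experimental group; see
#'   [mu_preset()].
#' @param lam microglia-to-pro-tumor conversion coefficient (per day per
#'   cell, through the saturating term).
#' @param K_lam Michaelis-Menten saturation constant of the conversion
#'   (cells).
#' @param phi MDM influx coefficient (per day); escalated at each IR
#'   fraction.
#' @param xi microglia recruitment coupling to tumor expansion
#'   (cells recruited per new tumor cell).
#' @param tau_M macrophage lifespan time constant (days).
#' @param K carrying capacity (mm^3).
#' @param v_T unit volume of one tumor cell (mm^3).
#' @param v_M unit volume of one macrophage (mm^3); also used for damaged
#'   cells.
#' @param tau_TD damaged-tumor-cell clearance time constant (days).
#' @param tau_MD damaged-macrophage clearance time constant (days).
#' @param S_M macrophage survival fraction per IR fraction, in `[0, 1]`.
#' @param phi_D inflammation flux coefficient from damaged cells to the
#'   anti-tumor pool (per day).
#' @param conversion_form algebraic form of the saturating conversion term:
#'   `"saturated"` gives `lam * A * T * K_lam / (K_lam + T)` (saturates at
#'   `lam * A * K_lam` for large tumors), `"michaelis"` gives
#'   `lam * A * T / (K_lam + T)`.
#' @param clamp_recruitment if `TRUE` (default) the microglia recruitment
#'   term `xi * dT/dt` only acts while the tumor expands (`dT/dt > 0`);
#'   shrinkage does not de-recruit microglia.
#'
#' @return An object of class `model_params` (a validated named list).
#' @seealso [mu_preset()], [population_state()], [simulate_population()]
#' @export
model_params <- function(rho_T = 1.6e-4,
                         rho_P = 5e-10,
                         rho_A = 1e-10,
                         mu = mu_preset("control"),
                         lam = 2e-7,
                         K_lam = 1e5,
                         phi = 7e-5,
                         xi = 1e-5,
                         tau_M = 15,
                         K = 1000,
                         v_T = 1e-6,
                         v_M = 5e-6,
                         tau_TD = 3,
                         tau_MD = 3,
                         S_M = 0.9,
                         phi_D = 1e-3,
                         conversion_form = c("saturated", "michaelis"),
                         clamp_recruitment = TRUE) {
  conversion_form <- match.arg(conversion_form)
  p <- list(rho_T = rho_T, rho_P = rho_P, rho_A = rho_A, mu = mu,
            lam = lam, K_lam = K_lam, phi = phi, xi = xi, tau_M = tau_M,
            K = K, v_T = v_T, v_M = v_M, tau_TD = tau_TD, tau_MD = tau_MD,
            S_M = S_M, phi_D = phi_D,
            conversion_form = conversion_form,
            clamp_recruitment = clamp_recruitment)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  pos <- c("rho_T", "rho_P", "rho_A", "mu", "K_lam", "tau_M", "K",
           "v_T", "v_M", "tau_TD", "tau_MD")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop(sprintf("parameter '%s' must be a single strictly positive number",
                   nm), call. = FALSE)
    }
  }
  for (nm in c("phi", "phi_D", "xi")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0) {
      stop(sprintf("parameter '%s' must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(p$lam) || length(p$lam) != 1L || !is.finite(p$lam)) {
    stop("parameter 'lam' must be a single finite number", call. = FALSE)
  }
  if (p$S_M < 0 || p$S_M > 1) {
    stop("'S_M' must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Group-specific presets for the macrophage killing rate
#'
#' The volumetric dynamics of untreated and irradiated cohorts are only
#' reconciled by markedly different macrophage killing rates: small early
#' control tumors sit in a microenvironment where anti-tumor macrophages
#' oppose growth effectively, while the larger irradiated tumors have an
#' immunosuppressed microenvironment with near-negligible killing. The two
#' presets (1.2e-4 and 5e-7 per day per cell) encode that regime switch and
#' are selected by experimental group, never silently.
#'
#' @param group `"control"` or `"treated"`.
#' @return The killing rate `mu` (per day per cell) for that group.
#' @export
mu_preset <- function(group = c("control", "treated")) {
  group <- match.arg(group)
  switch(group, control = 1.2e-4, treated = 5e-7)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  num <- vapply(x, is.numeric, logical(1))
  vals <- unlist(x[num])
  cat(paste0("  ", format(names(vals)), " = ", signif(vals, 6),
             collapse = "\n"), "\n")
  cat("  conversion_form  =", x$conversion_form, "\n")
  cat("  clamp_recruitment =", x$clamp_recruitment, "\n")
  invisible(x)
}

#' Replace fields of a parameter set
#'
#' @param params a [model_params()] object.
#' @param ... named fields to replace.
#' @return A new validated `model_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  mod <- list(...)
  bad <- setdiff(names(mod), names(params))
  if (length(bad)) {
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  params[names(mod)] <- mod
  validate_model_params(params)
  params
}
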