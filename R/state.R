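#' Instantaneous cell counts of the model compartments
#'
#' The six compartments are tumor cells (`T`), microglia-derived pro-tumor
#' macrophages (`P1`), MDM-derived pro-tumor macrophages (`P2`), anti-tumor
#' macrophages (`A`), damaged tumor cells (`TD`) and damaged macrophages
#' (`MD`). The pro-tumor pool of the three-population model is `P = P1 + P2`
#' exactly; the split only attributes provenance and never changes pooled
#' dynamics.
#'
#' @param T tumor cells (count, >= 0).
#' @param P1 microglia-derived pro-tumor macrophages (count, >= 0).
#' @param P2 MDM-derived pro-tumor macrophages (count, >= 0).
#' @param A anti-tumor macrophages (count, >= 0).
#' @param TD damaged tumor cells (count, >= 0).
#' @param MD damaged macrophages (count, >= 0).
#' @return A named numeric vector of class `population_state`.
#' @export
population_state <- function(T = 0, P1 = 0, P2 = 0, A = 0, TD = 0, MD = 0) {
  s <- c(T = T, P1 = P1, P2 = P2, A = A, TD = TD, MD = MD)
  if (!all(is.finite(s))) stop("all compartments must be finite", call. = FALSE)
  if (any(s < 0)) {
    stop("all compartments must be non-negative; offending: ",
         paste(names(s)[s < 0], collapse = ", "), call. = FALSE)
  }
  structure(s, class = "population_state")
}

state_names <- c("T", "P1", "P2", "A", "TD", "MD")

as_state_vector <- function(state) {
  s <- unclass(state)
  if (is.null(names(s)) && length(s) == 6L) names(s) <- state_names
  s[state_names]
}

#' Tumor volume of a population state
#'
#' Total volume is the sum of the compartments weighted by their unit
#' volumes: `v_T * (T + TD) + v_M * (P1 + P2 + A + MD)`. Damaged cells keep
#' contributing to volume until cleared; before any irradiation `TD = MD = 0`
#' and the law reduces to the undamaged three-population volume.
#'
#' @param state a [population_state()] (or named numeric vector with the six
#'   compartments).
#' @param params a [model_params()] object supplying `v_T` and `v_M`.
#' @return Volume in mm^3.
#' @export
volume <- function(state, params) {
  s <- as_state_vector(state)
  unname(params$v_T * (s[["T"]] + s[["TD"]]) +
           params$v_M * (s[["P1"]] + s[["P2"]] + s[["A"]] + s[["MD"]]))
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state>\n")
  print(unclass(x))
  invisible(x)
}
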