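# Independent fixed-step oracles and small fixtures used across tests.

# Classical fixed-step RK4 over [t0, t1]. Deliberately shares nothing with
# the adaptive integration path except the model right-hand side, so it
# serves as a brute-force integration oracle.
rk4_oracle <- function(state, params, t0, t1, dt,
                       modifiers = list(mu_multiplier = 1,
                                        influx_attenuation = 1,
                                        lambda_override = NULL),
                       ir_active = FALSE, keep_times = NULL) {
  f <- function(s) unclass(population_rhs(0, s, params, modifiers,
                                          ir_active))
  n <- ceiling((t1 - t0) / dt)
  y <- as.numeric(state)[1:6]
  names(y) <- c("T", "P1", "P2", "A", "TD", "MD")
  out_t <- t0
  out_y <- list(y)
  tt <- t0
  for (i in seq_len(n)) {
    h <- min(dt, t1 - tt)
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tt <- tt + h
    if (is.null(keep_times) || any(abs(keep_times - tt) < dt / 2)) {
      out_t <- c(out_t, tt)
      out_y[[length(out_y) + 1]] <- y
    }
  }
  list(times = out_t, states = do.call(rbind, out_y))
}

# Parameter set used throughout the tests: package defaults with a control
# killing-rate preset, unless overridden.
test_params <- function(...) {
  update_params(model_params(), ...)
}

# A small strictly positive state away from any boundary.
test_state <- function() {
  population_state(T = 2.5e6, P1 = 8e3, P2 = 7e3, A = 9e4, TD = 1e4,
                   MD = 2e3)
}

# Hand product-limit Kaplan-Meier for uncensored or censored samples,
# computed by direct enumeration of risk sets (used only on tiny n).
hand_km <- function(times, censored = rep(FALSE, length(times))) {
  ord <- order(times)
  times <- times[ord]; censored <- censored[ord]
  ev_times <- sort(unique(times[!censored]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (k in seq_along(ev_times)) {
    tk <- ev_times[k]
    n_risk <- sum(times >= tk)
    d <- sum(times == tk & !censored)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ev_times, surv = surv)
}

# Hand two-group log-rank chi-square by direct enumeration of the 2x2 risk
# tables at each distinct event time.
hand_logrank <- function(ta, tb, ca = rep(FALSE, length(ta)),
                         cb = rep(FALSE, length(tb))) {
  times <- c(ta, tb); cens <- c(ca, cb)
  grp <- rep(c(0, 1), c(length(ta), length(tb)))
  ev <- sort(unique(times[!cens]))
  O <- 0; E <- 0; V <- 0
  for (tk in ev) {
    at_risk <- times >= tk
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 0)
    d <- sum(times == tk & !cens)
    d1 <- sum(times == tk & !cens & grp == 0)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(statistic = chisq, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}
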