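test_that("initial-state allocation follows the volume-fraction formulas", {
  p <- test_params(v_T = 1e-6, v_M = 1e-6)
  fr <- initial_fractions(0.96, 0.035, 0.005)
  s <- allocate_initial_state(3, fr, p)
  # with v_T = v_M = v the denominator is v and X0 = f_X * V0 / v
  expect_equal(unname(s[["T"]]), 2.88e6)
  expect_equal(unname(s[["A"]]), 1.05e5)
  expect_equal(unname(s[["P1"]]), 7.5e3)
  expect_equal(unname(s[["P2"]]), 7.5e3)
  expect_identical(unname(s[["TD"]]), 0)

  # unequal unit volumes: general denominator
  p2 <- test_params(v_T = 1e-6, v_M = 5e-6)
  s2 <- allocate_initial_state(3, fr, p2)
  den <- 1e-6 * 0.96 + 5e-6 * 0.04
  expect_equal(unname(s2[["T"]]), 0.96 * 3 / den, tolerance = 1e-12)
})

test_that("allocation reconstructs the observed volume exactly", {
  set.seed(31)
  for (i in 1:25) {
    p <- test_params(v_T = runif(1, 5e-7, 5e-6), v_M = runif(1, 5e-7, 1e-5))
    f <- runif(3); f <- f / sum(f)
    fr <- initial_fractions(f[1], f[2], f[3])
    V0 <- runif(1, 0.5, 100)
    s <- allocate_initial_state(V0, fr, p)
    expect_equal(volume(s, p), V0, tolerance = 1e-12)
  }
})

test_that("fraction constructors validate their invariants", {
  expect_error(initial_fractions(0.9, 0.2, 0.005), "sum to 1")
  expect_error(initial_fractions(-0.1, 1.05, 0.05), "\\[0, 1\\]")
  expect_error(allocate_initial_state(0, initial_fractions(),
                                      test_params()), "V0")
})

make_fraction_trajectory <- function(p, rels, line) {
  # build a trajectory whose fractions follow known lines of rel volume
  V <- rels * 500
  f_T <- line$f_T[1] + line$f_T[2] * rels
  f_A <- line$f_A[1] + line$f_A[2] * rels
  f_P <- 1 - f_T - f_A
  states <- cbind(T = f_T * V / p$v_T, P1 = f_P * V / p$v_M / 2,
                  P2 = f_P * V / p$v_M / 2, A = f_A * V / p$v_M,
                  TD = 0, MD = 0)
  structure(list(times = seq_along(rels) - 1, states = states,
                 volume = V, params = p,
                 event_log = data.frame(), horizon = length(rels) - 1),
            class = "population_trajectory")
}

test_that("proportion regression recovers generating lines exactly", {
  p <- test_params(v_T = 1e-6, v_M = 1e-6)
  line <- list(f_T = c(0.90, 0.08), f_A = c(0.06, -0.05))
  rels <- seq(0.1, 1, length.out = 10)
  tr1 <- make_fraction_trajectory(p, rels, line)
  tr2 <- make_fraction_trajectory(p, seq(0.2, 1, length.out = 8), line)
  maps <- proportion_regression(list(tr1, tr2))
  expect_equal(unname(maps$coef$f_T), c(0.90, 0.08), tolerance = 1e-6)
  expect_equal(unname(maps$coef$f_A), c(0.06, -0.05), tolerance = 1e-6)
  fr <- predict_fractions(maps, 0.5)
  expect_equal(fr$f_T, 0.90 + 0.08 * 0.5, tolerance = 1e-6)
  expect_equal(fr$f_T + fr$f_A + fr$f_P, 1, tolerance = 1e-12)
})

test_that("constant fractions give zero-slope maps returning themselves", {
  p <- test_params(v_T = 1e-6, v_M = 1e-6)
  line <- list(f_T = c(0.95, 0), f_A = c(0.03, 0))
  tr <- make_fraction_trajectory(p, seq(0.1, 1, length.out = 12), line)
  maps <- proportion_regression(list(tr))
  expect_equal(unname(maps$coef$f_T[2]), 0, tolerance = 1e-9)
  fr <- predict_fractions(maps, 0.33)
  expect_equal(fr$f_T, 0.95, tolerance = 1e-6)
  expect_equal(fr$f_A, 0.03, tolerance = 1e-6)
})

test_that("degenerate predictors are rejected", {
  p <- test_params(v_T = 1e-6, v_M = 1e-6)
  states <- cbind(T = rep(9e8, 4), P1 = 0, P2 = 0, A = 0, TD = 0, MD = 0)
  tr <- structure(list(times = 0:3, states = states,
                       volume = rep(900, 4), params = p,
                       event_log = data.frame(), horizon = 3),
                  class = "population_trajectory")
  expect_error(proportion_regression(list(tr)), "degenerate")
})

make_control_record <- function(id, rho_T, V0 = 3,
                                times = c(0, 1.5, 3, 4.5, 6, 7.5)) {
  p <- update_params(model_params(), mu = mu_preset("control"),
                     rho_T = rho_T)
  init <- allocate_initial_state(V0, initial_fractions(), p)
  tr <- simulate_population(init, p, NULL, horizon = max(times),
                            output_grid = sort(unique(c(
                              seq(0, max(times), length.out = 101),
                              times))))
  subject_record(id, "control", times, volume_at(tr, times))
}

test_that("the control fit recovers a known proliferation rate", {
  rho_true <- 1.4e-4
  rec <- make_control_record("c1", rho_true)
  fit <- fit_control(rec, update_params(model_params(),
                                        mu = mu_preset("control")))
  expect_lt(abs(fit$rho_T / rho_true - 1), 1e-3)
  # near-zero residual relative to the volume scale of the record
  expect_lt(fit$rmse, 1e-3 * max(rec$volumes))
  # objective correctness: reported value equals RMSE of the residuals
  expect_equal(fit$rmse, sqrt(mean(fit$residuals^2)), tolerance = 1e-10)
})

test_that("fits preserve the ordering of generating rates", {
  rec_slow <- make_control_record("slow", 0.8e-4)
  rec_fast <- make_control_record("fast", 1.6e-4)
  fx <- update_params(model_params(), mu = mu_preset("control"))
  f_slow <- fit_control(rec_slow, fx, n_starts = 1)
  f_fast <- fit_control(rec_fast, fx, n_starts = 1)
  expect_lt(f_slow$rho_T, f_fast$rho_T)
})

test_that("log-scale and box-constrained fits agree on a clean case", {
  rec <- make_control_record("c2", 1.5e-4)
  fx <- update_params(model_params(), mu = mu_preset("control"))
  fit_log <- fit_control(rec, fx, n_starts = 1)
  obj_nat <- function(r) {
    tryCatch(
      gliomatwin:::volume_rmse(rec, update_params(fx, rho_T = r), NULL,
                               initial_fractions())$rmse,
      error = function(e) 1e12)
  }
  o <- stats::optim(fx$rho_T, obj_nat, method = "L-BFGS-B",
                    lower = 1e-6, upper = 1e-2,
                    control = list(factr = 1e4,
                                   parscale = fx$rho_T))
  expect_lt(abs(fit_log$rho_T / o$par - 1), 1e-3)
})

test_that("the treated fit recovers rate and radiosensitivity jointly", {
  fx_c <- update_params(model_params(), mu = mu_preset("control"))
  fx_t <- update_params(model_params(), mu = mu_preset("treated"))
  # proportion maps from two known control trajectories
  trajs <- lapply(c(1.3e-4, 1.6e-4), function(r) {
    p <- update_params(fx_c, rho_T = r)
    init <- allocate_initial_state(3, initial_fractions(), p)
    simulate_population(init, p, NULL, horizon = 8,
                        output_grid = seq(0, 8, length.out = 101))
  })
  maps <- proportion_regression(trajs)
  ref_max <- 600
  rho_true <- 6e-7; st_true <- 0.55; V0 <- 45
  fr <- predict_fractions(maps, V0 / ref_max)
  p_true <- update_params(fx_t, rho_T = rho_true)
  init <- allocate_initial_state(V0, fr, p_true)
  times <- c(0, 3, 7, 11, 15, 19)
  tr <- simulate_population(init, p_true, schedule(1:5, st_true),
                            horizon = max(times),
                            output_grid = sort(unique(c(
                              seq(0, max(times), length.out = 101),
                              times))))
  rec <- subject_record("t1", "treated", times, volume_at(tr, times))
  fit <- fit_treated(rec, fx_t, ir_course(1, S_T = 0.5), maps, ref_max)
  expect_lt(abs(fit$rho_T / rho_true - 1), 0.01)
  expect_lt(abs(fit$S_T / st_true - 1), 0.01)
  expect_lt(fit$rmse, 0.05)

  # an undetectable treatment effect fits a survival fraction near 1
  tr1 <- simulate_population(init, p_true, schedule(1:5, 1),
                             horizon = max(times),
                             output_grid = sort(unique(c(
                               seq(0, max(times), length.out = 101),
                               times))))
  rec1 <- subject_record("t2", "treated", times, volume_at(tr1, times))
  fit1 <- fit_treated(rec1, fx_t, ir_course(1, S_T = 0.5), maps, ref_max,
                      n_starts = 1)
  expect_gte(fit1$S_T, 0.95)
})

test_that("records with too few points are rejected", {
  rec <- subject_record("x", "control", c(0, 2), c(3, 5))
  expect_error(fit_control(rec, model_params()), "3 observation")
  expect_error(subject_record("y", "control", c(0, 1), c(3, -1)),
               "positive")
  expect_error(subject_record("z", "control", c(0, 0.5, 0.2), c(1, 2, 3)),
               "increasing")
})
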