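#' Digital twin of a fitted subject
#'
#' A per-subject parameterization of the model used to simulate
#' counterfactual treatment arms: the shared fixed parameters with the
#' subject's fitted proliferation rate, the fitted radiosensitivity, the
#' allocated initial state, and a death-volume threshold set to the last
#' observed (or ground-truth) volume increased by 20%.
#'
#' @param subject_id identifier.
#' @param params a [model_params()] with the subject's `rho_T` (and the
#'   group-appropriate killing-rate preset).
#' @param S_T fitted per-fraction tumor survival fraction (`NA` for
#'   untreated subjects; a trial arm supplies its own when needed).
#' @param initial a [population_state()].
#' @param death_threshold volume (mm^3) whose first crossing defines the
#'   twin's death.
#' @param reference_schedule the [schedule()] the subject was fitted under
#'   (or `NULL`).
#' @return An object of class `digital_twin`.
#' @export
digital_twin <- function(subject_id, params, S_T, initial, death_threshold,
                         reference_schedule = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (death_threshold <= 0) {
    stop("'death_threshold' must be > 0", call. = FALSE)
  }
  if (death_threshold <= volume(initial, params)) {
    stop("death threshold (", death_threshold,
         " mm^3) must exceed the initial volume", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), params = params,
                 S_T = S_T, initial = initial,
                 death_threshold = death_threshold,
                 reference_schedule = reference_schedule),
            class = "digital_twin")
}

#' Build digital twins from a fitted cohort
#'
#' @param cohort_fit a `cohort_fit` from [fit_cohort()].
#' @param group which group to build twins for (default `"treated"`, the
#'   usual trial population).
#' @return List of `digital_twin` objects. Each twin's death threshold is
#'   1.2 times the subject's last observed volume.
#' @export
twins_from_fit <- function(cohort_fit, group = "treated") {
  fits <- Filter(function(f) f$group == group, cohort_fit$fits)
  lapply(fits, function(f) {
    mu <- mu_preset(f$group)
    p <- update_params(cohort_fit$fixed, rho_T = f$rho_T, mu = mu)
    init <- allocate_initial_state(f$record$first_volume, f$fractions, p)
    vols <- f$record$volumes
    # 20% above the last observation, and always above the initial volume
    # so death cannot precede the start of the simulation
    digital_twin(f$subject_id, p, f$S_T, init,
                 death_threshold = 1.2 * max(vols[length(vols)], vols[1]),
                 reference_schedule = f$schedule)
  })
}

#' Build digital twins from a synthetic cohort's ground truth
#'
#' Uses the generating parameters directly (no fitting), with death
#' thresholds of 1.2 times the final true sampled volume.
#'
#' @param cohort a `synthetic_cohort`.
#' @param group group to build twins for.
#' @return List of `digital_twin` objects.
#' @export
twins_from_truth <- function(cohort, group = "treated") {
  tr <- cohort$truth[cohort$truth$group == group, , drop = FALSE]
  lapply(seq_len(nrow(tr)), function(i) {
    row <- tr[i, ]
    p <- update_params(cohort$spec$params, rho_T = row$true_rho_T,
                       mu = mu_preset(row$group))
    fr <- if (row$group == "control") initial_fractions() else
      predict_fractions(cohort$maps, row$V0 / cohort$ref_max_volume)
    init <- allocate_initial_state(row$V0, fr, p)
    digital_twin(row$subject_id, p, row$true_S_T, init,
                 death_threshold = row$death_threshold)
  })
}

#' Death time of a simulated trajectory
#'
#' The first time the tumor volume exceeds the threshold, refined between
#' the bracketing grid points by bisection on the (log-scale) interpolated
#' volume to 0.01-day precision. Censored at the horizon if never crossed.
#'
#' @param traj a `population_trajectory`.
#' @param threshold volume threshold (mm^3, > 0).
#' @return A list with `time` (days) and `censored` (logical).
#' @export
death_time <- function(traj, threshold) {
  if (threshold <= 0) stop("'threshold' must be > 0", call. = FALSE)
  v <- traj$volume
  tt <- traj$times
  above <- v > threshold
  if (above[1]) return(list(time = tt[1], censored = FALSE))
  idx <- which(above)
  if (!length(idx)) {
    return(list(time = tt[length(tt)], censored = TRUE))
  }
  i <- min(idx)
  t_lo <- tt[i - 1]; t_hi <- tt[i]
  # volume is locally near-exponential; interpolate on the log scale over
  # the fixed bracketing grid interval
  f <- function(x) {
    exp(stats::approx(c(t_lo, t_hi), log(c(v[i - 1], v[i])),
                      xout = x)$y) - threshold
  }
  lo <- t_lo; hi <- t_hi
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  list(time = (lo + hi) / 2, censored = FALSE)
}

#' Kaplan-Meier estimate with 95% confidence bounds
#'
#' Product-limit estimator with Greenwood variance and log-log transformed
#' confidence bounds.
#'
#' @param times event or censoring times.
#' @param censored logical; `TRUE` where the time is censored.
#' @return A data.frame with `time`, `n_risk`, `n_event`, `surv`, `lower`,
#'   `upper`, plus the median survival as attribute `"median"`.
#' @export
km_estimate <- function(times, censored = rep(FALSE, length(times))) {
  fit <- survival::survfit(
    survival::Surv(times, !censored) ~ 1, conf.type = "log-log")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    lower = fit$lower, upper = fit$upper)
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  attr(out, "median") <- med
  out
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank test with one degree of freedom comparing
#' observed and expected events under the null of equal survival.
#'
#' @param times_a,times_b event/censoring times per group.
#' @param censored_a,censored_b censoring flags per group.
#' @return A list with `statistic` and `p_value`.
#' @export
logrank_test <- function(times_a, times_b,
                         censored_a = rep(FALSE, length(times_a)),
                         censored_b = rep(FALSE, length(times_b))) {
  time <- c(times_a, times_b)
  event <- c(!censored_a, !censored_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  if (all(times_a == times_b) && all(censored_a == censored_b)) {
    # identical arms: observed = expected, chi-square is exactly 0
    return(list(statistic = 0, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- unname(sd$chisq)
  list(statistic = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cohen's d with noncentral-t confidence interval
#'
#' Standardized mean difference (first group minus second, pooled SD), with
#' a 95% confidence interval obtained by inverting the noncentral-t
#' distribution of the associated t statistic. When the interval contains
#' zero the effect is labelled inconclusive (`"inc"`).
#'
#' @param x,y numeric samples.
#' @param conf confidence level (default 0.95).
#' @return A list with `d`, `ci` (length 2), and `label` (`"inc"` or
#'   `"conclusive"`).
#' @export
cohens_d <- function(x, y, conf = 0.95) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group",
                             call. = FALSE)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    d <- 0
    ci <- c(0, 0)
  } else {
    d <- (mean(x) - mean(y)) / sp
    scale <- sqrt(1 / n1 + 1 / n2)
    tobs <- d / scale
    df <- n1 + n2 - 2
    alpha <- 1 - conf
    # noncentrality bounds: pt(tobs; df, ncp) = 1 - alpha/2 resp. alpha/2
    ncp_bound <- function(p) {
      # pt() warns about tail precision for large noncentrality; uniroot's
      # tolerance dominates the achievable accuracy here
      f <- function(ncp) suppressWarnings(stats::pt(tobs, df,
                                                    ncp = ncp)) - p
      lo <- tobs - 10 * (1 + abs(tobs)); hi <- tobs + 10 * (1 + abs(tobs))
      while (f(lo) < 0) lo <- lo - 10 * (1 + abs(tobs))
      while (f(hi) > 0) hi <- hi + 10 * (1 + abs(tobs))
      stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
    }
    ci <- sort(c(ncp_bound(1 - alpha / 2), ncp_bound(alpha / 2))) * scale
  }
  label <- if (ci[1] <= 0 && ci[2] >= 0) "inc" else "conclusive"
  list(d = d, ci = ci, label = label)
}

#' Paired digital-twin trial between two treatment arms
#'
#' Simulates every twin under both arms with identical solver settings and
#' death criterion, and reports per-twin paired survival gains alongside
#' the unpaired Kaplan-Meier/log-rank comparison. Because both arms contain
#' the same twins, a paired gain is meaningful even when the unpaired
#' log-rank test (designed for randomized groups) is not significant.
#'
#' When an arm includes radiation fractions and the arm's `S_T` is `NA`,
#' each twin's own fitted `S_T` is used, so one schedule template can serve
#' a whole heterogeneous cohort.
#'
#' @param twins list of [digital_twin()]s.
#' @param arm_a,arm_b [schedule()]s (e.g. `schedule()` for no treatment and
#'   [ir_course()] for the standard course).
#' @param horizon simulation horizon (days); twins not crossing their
#'   threshold by then are censored.
#' @param control solver settings.
#' @param output_dt trajectory grid step (days) used for death-time
#'   bracketing.
#' @return An object of class `trial_result`: per-twin death times and
#'   censoring per arm, per-twin gains (`arm_b` minus `arm_a`), KM curves
#'   with medians, the log-rank test, and the arm schedules.
#' @export
run_trial <- function(twins, arm_a, arm_b, horizon,
                      control = solver_control(), output_dt = 0.25) {
  sim_arm <- function(twin, arm) {
    sch <- resolve_arm(arm, twin)
    tr <- tryCatch(
      simulate_population(twin$initial, twin$params, sch, horizon = horizon,
                          output_grid = seq(0, horizon, by = output_dt),
                          control = control),
      error = function(e) stop("simulation failed for twin '",
                               twin$subject_id, "': ", conditionMessage(e),
                               call. = FALSE))
    death_time(tr, twin$death_threshold)
  }
  res_a <- lapply(twins, sim_arm, arm = arm_a)
  res_b <- lapply(twins, sim_arm, arm = arm_b)
  ta <- vapply(res_a, `[[`, numeric(1), "time")
  tb <- vapply(res_b, `[[`, numeric(1), "time")
  ca <- vapply(res_a, `[[`, logical(1), "censored")
  cb <- vapply(res_b, `[[`, logical(1), "censored")
  ids <- vapply(twins, `[[`, character(1), "subject_id")
  km_a <- km_estimate(ta, ca)
  km_b <- km_estimate(tb, cb)
  lr <- logrank_test(ta, tb, ca, cb)
  gains <- tb - ta
  structure(list(
    subject_id = ids,
    death_a = ta, death_b = tb, censored_a = ca, censored_b = cb,
    gains = gains, median_gain = stats::median(gains),
    km_a = km_a, km_b = km_b,
    median_a = attr(km_a, "median"), median_b = attr(km_b, "median"),
    logrank = lr, arm_a = arm_a, arm_b = arm_b, horizon = horizon),
    class = "trial_result")
}

resolve_arm <- function(arm, twin) {
  stopifnot(inherits(arm, "schedule"))
  if (length(arm$ir_times) && is.na(arm$S_T)) {
    stop("arm schedule has NA S_T", call. = FALSE)
  }
  if (length(arm$ir_times) && !is.null(attr(arm, "use_twin_S_T")) &&
      attr(arm, "use_twin_S_T")) {
    if (is.na(twin$S_T)) {
      stop("twin '", twin$subject_id, "' has no fitted S_T", call. = FALSE)
    }
    return(schedule(arm$ir_times, twin$S_T, arm$therapies))
  }
  arm
}

#' Mark a schedule to use each twin's own fitted survival fraction
#'
#' @param sched a [schedule()] with radiation fractions.
#' @return The schedule, flagged so [run_trial()] substitutes each twin's
#'   fitted `S_T`.
#' @export
per_twin_S_T <- function(sched) {
  attr(sched, "use_twin_S_T") <- TRUE
  sched
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result> ", length(x$gains), " twins, horizon ", x$horizon,
      " d\n", sep = "")
  cat("  median survival: arm A ", x$median_a, " d, arm B ", x$median_b,
      " d\n", sep = "")
  cat("  median paired gain (B - A): ", x$median_gain, " d\n", sep = "")
  cat("  log-rank: chi-square = ", signif(x$logrank$statistic, 4),
      ", p = ", signif(x$logrank$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Survival-benefit map over protracted fractionation intervals
#'
#' Simulates each twin under courses whose inter-fraction interval varies,
#' and reports the per-twin survival gain relative to the daily course,
#' with group summaries at the 25th/50th/75th survival percentiles.
#'
#' @param twins list of [digital_twin()]s (must carry fitted `S_T`).
#' @param intervals inter-fraction intervals (days); the course with
#'   interval 1 (daily) is the reference and is added if missing.
#' @param start_day,n_fractions course geometry.
#' @param horizon simulation horizon (days).
#' @param control solver settings.
#' @param output_dt trajectory grid step (days).
#' @return A list of class `protraction_scan`: `benefit` (data.frame
#'   twin_id x interval_d with gain_d), `summary` (per interval: gains at
#'   the 25th/50th/75th percentile), `death_ref` (per-twin death under the
#'   daily course).
#' @export
protraction_scan <- function(twins, intervals = 2:9, start_day = 1,
                             n_fractions = 5, horizon,
                             control = solver_control(), output_dt = 0.25) {
  intervals <- sort(unique(c(1, intervals)))
  deaths <- matrix(NA_real_, nrow = length(twins),
                   ncol = length(intervals),
                   dimnames = list(vapply(twins, `[[`, character(1),
                                          "subject_id"),
                                   as.character(intervals)))
  for (j in seq_along(intervals)) {
    arm <- per_twin_S_T(ir_course(start_day = start_day,
                                  n_fractions = n_fractions,
                                  interval_days = intervals[j], S_T = 0.5))
    for (i in seq_along(twins)) {
      sch <- resolve_arm(arm, twins[[i]])
      tr <- simulate_population(twins[[i]]$initial, twins[[i]]$params, sch,
                                horizon = horizon,
                                output_grid = seq(0, horizon,
                                                  by = output_dt),
                                control = control)
      deaths[i, j] <- death_time(tr, twins[[i]]$death_threshold)$time
    }
  }
  ref <- deaths[, "1"]
  gains <- deaths - ref
  benefit <- data.frame(
    twin_id = rep(rownames(deaths), times = ncol(deaths)),
    interval_d = rep(intervals, each = nrow(deaths)),
    gain_d = as.vector(gains))
  summary <- do.call(rbind, lapply(seq_along(intervals), function(j) {
    data.frame(interval_d = intervals[j],
               q25 = unname(stats::quantile(gains[, j], 0.25)),
               median = stats::median(gains[, j]),
               q75 = unname(stats::quantile(gains[, j], 0.75)))
  }))
  structure(list(benefit = benefit, summary = summary, deaths = deaths,
                 death_ref = ref, intervals = intervals),
            class = "protraction_scan")
}

#' Does the proliferation rate predict treatment benefit?
#'
#' Ordinary least-squares regression of the per-twin survival gain on
#' `log(rho_T)` (with R-squared and the F-test p-value), and the ROC AUC of
#' `rho_T` as a binary classifier of the benefit split. The AUC is the
#' normalized Mann-Whitney rank statistic. For therapy analyses the split
#' is at the median gain (`split = "median"`); for protraction it is the
#' sign of the gain (`split = "sign"`).
#'
#' @param rho_T per-twin fitted proliferation rates.
#' @param gains per-twin survival gains (days).
#' @param split `"median"` or `"sign"`.
#' @return A list with `r_squared`, `f_p_value`, `slope`, `intercept`,
#'   `auc`, `high_group` (logical vector of the high-benefit class), and
#'   the effect size of `rho_T` between benefit groups (`effect`).
#' @export
benefit_predictor <- function(rho_T, gains, split = c("median", "sign")) {
  split <- match.arg(split)
  stopifnot(length(rho_T) == length(gains))
  fit <- stats::lm(gains ~ log(rho_T))
  sm <- summary(fit)
  fp <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  high <- if (split == "median") gains > stats::median(gains) else gains > 0
  auc <- if (length(unique(high)) < 2) NA_real_ else
    rank_auc(rho_T, high)
  effect <- if (sum(high) >= 2 && sum(!high) >= 2) {
    cohens_d(rho_T[high], rho_T[!high])
  } else NULL
  list(r_squared = sm$r.squared, f_p_value = fp,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       auc = auc, high_group = high, effect = effect)
}

# AUC as the normalized Mann-Whitney U statistic of `score` for the
# positive class, with the 0.5 tie correction.
rank_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  u <- sum(vapply(pos, function(s) {
    sum(s > neg) + 0.5 * sum(s == neg)
  }, numeric(1)))
  u / (length(pos) * length(neg))
}
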