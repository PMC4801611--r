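# Performance metrics, the multi-start evaluation protocol, parameter
# optimization, and the filter x calibration factorial experiment.

#' Mean (absolute) error between an estimate and a reference
#'
#' `ME = (1/N) * sum(|theta_hat - theta_ref|)`, degrees.
#'
#' @param est,ref Numeric vectors of equal length.
#' @return The mean absolute error.
#' @export
mean_error <- function(est, ref) {
  if (length(est) != length(ref)) {
    stop("estimate and reference must have equal length", call. = FALSE)
  }
  if (length(est) == 0) stop("empty series", call. = FALSE)
  mean(abs(est - ref))
}

#' Root mean square error between an estimate and a reference
#'
#' `RMSE = sqrt((1/N) * sum((theta_hat - theta_ref)^2))`, degrees.
#'
#' @param est,ref Numeric vectors of equal length.
#' @return The root mean square error.
#' @export
rmse <- function(est, ref) {
  if (length(est) != length(ref)) {
    stop("estimate and reference must have equal length", call. = FALSE)
  }
  if (length(est) == 0) stop("empty series", call. = FALSE)
  sqrt(mean((est - ref)^2))
}

#' Multi-start evaluation protocol
#'
#' The trial is split into disjoint optimization and validation windows
#' (head and tail outside the windows are discarded).  Within each window,
#' `n_start` filter start points are placed uniformly over its first three
#' quarters; every (optimization start, validation start) pair forms one
#' evaluation cell, so `n_start^2` combinations are scored per filter.
#'
#' @param opt_window,val_window Two-element `c(from_s, to_s)` windows in
#'   seconds; must be disjoint.
#' @param n_start Number of start points per phase (default 6).
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(opt_window = c(10, 30), val_window = c(30, 50),
                          n_start = 6) {
  stopifnot(length(opt_window) == 2, length(val_window) == 2,
            diff(opt_window) > 0, diff(val_window) > 0, n_start >= 1)
  if (opt_window[2] > val_window[1] && val_window[2] > opt_window[1]) {
    if (!(opt_window[2] <= val_window[1] || val_window[2] <= opt_window[1])) {
      stop("optimization and validation windows must be disjoint",
           call. = FALSE)
    }
  }
  starts <- function(w, n) {
    if (n == 1) w[1] else seq(w[1], w[1] + 0.75 * diff(w), length.out = n)
  }
  structure(
    list(opt_window = opt_window, val_window = val_window,
         n_start = as.integer(n_start),
         opt_starts = starts(opt_window, n_start),
         val_starts = starts(val_window, n_start)),
    class = "eval_protocol"
  )
}

# internal: cut a recording / pot series / angle series to [from_s, end]
slice_recording <- function(rec, from_s) {
  keep <- rec$times >= from_s - 1e-9
  rec$times <- rec$times[keep] - rec$times[keep][1]
  rec$temperature <- rec$temperature[keep]
  for (s in names(rec$segments)) {
    rec$segments[[s]]$accel <- rec$segments[[s]]$accel[keep, , drop = FALSE]
    rec$segments[[s]]$gyro <- rec$segments[[s]]$gyro[keep, , drop = FALSE]
  }
  rec
}

slice_pots <- function(pots, from_s) {
  keep <- pots$times >= from_s - 1e-9
  pots$joints <- pots$joints[keep, , drop = FALSE]
  pots$times <- pots$times[keep] - pots$times[keep][1]
  pots
}

#' Score a filter run against ground truth over a time window
#'
#' @param result A [run_filter()] result.
#' @param truth A [segment_angle_series()] ground truth on the same clock
#'   as the recording the filter ran on.
#' @param window Two-element window `c(from_s, to_s)` on the truth clock,
#'   or `NULL` for the full overlap.
#' @param offset_s Time by which the filter run is shifted relative to the
#'   truth clock (the run's start time).
#' @return Data frame with one row per segment: `segment`, `rmse`, `me`.
#' @export
score_filter <- function(result, truth, window = NULL, offset_s = 0) {
  stopifnot(inherits(result, "kf_result"),
            inherits(truth, "segment_angle_series"))
  est_times <- result$est$times + offset_s
  if (is.null(window)) window <- range(est_times)
  keep_t <- truth$times >= window[1] - 1e-9 & truth$times <= window[2] + 1e-9
  idx <- match(round(truth$times[keep_t] * truth$rate),
               round(est_times * truth$rate))
  ok <- !is.na(idx)
  if (!any(ok)) stop("no overlap between estimate and scoring window",
                     call. = FALSE)
  ref <- truth$angles[keep_t, , drop = FALSE][ok, , drop = FALSE]
  est <- result$est$angles[idx[ok], , drop = FALSE]
  data.frame(
    segment = colnames(ref),
    rmse = vapply(seq_len(ncol(ref)), function(j) rmse(est[, j], ref[, j]),
                  numeric(1)),
    me = vapply(seq_len(ncol(ref)), function(j) mean_error(est[, j], ref[, j]),
                numeric(1)),
    row.names = NULL
  )
}

#' Optimize filter parameters by differential evolution
#'
#' Minimizes the mean validation-window RMSE across the protocol's
#' optimization start points.  A small differential-evolution population
#' search stands in for the genetic optimizer used in gait studies; the
#' optimizer is generic and deterministic given `seed`.
#'
#' @param filter Filter kind, see [run_filter()].
#' @param rec Physical-unit `imu_recording` of the trial.
#' @param truth Ground-truth [segment_angle_series()].
#' @param lower,upper Named numeric vectors bounding the searched
#'   parameters (any of `tau_g`, `sigma_g`, `sigma_bg`, `sigma_meas`,
#'   `sigma_pot`, `zeta`).
#' @param pots `pot_series` (Markovian filter only).
#' @param protocol An [eval_protocol()].
#' @param budget Total number of objective evaluations.
#' @param seed Integer seed.
#' @param fixed Named list of parameters held fixed.
#' @return List with `par` (named best parameters), `value` (best
#'   objective), and `evals`.
#' @export
optimize_params <- function(filter, rec, truth, lower, upper, pots = NULL,
                            protocol = eval_protocol(), budget = 60,
                            seed = 1L, fixed = list()) {
  stopifnot(length(lower) == length(upper), !is.null(names(lower)),
            all(names(lower) == names(upper)), all(upper >= lower))
  if (length(lower) == 0) stop("empty search space", call. = FALSE)
  nm <- names(lower)
  d <- length(nm)
  objective <- function(par) {
    p <- as.list(setNames(par, nm))
    zeta <- if (!is.null(p$zeta)) p$zeta else
      if (!is.null(fixed$zeta)) fixed$zeta else 0.4
    p$zeta <- NULL
    params <- modifyList(fixed[setdiff(names(fixed), "zeta")], p)
    vals <- vapply(protocol$opt_starts, function(s0) {
      res <- run_filter(slice_recording(rec, s0),
                        pots = if (!is.null(pots)) slice_pots(pots, s0),
                        filter = filter, params = params, zeta = zeta)
      mean(score_filter(res, truth, window = protocol$val_window,
                        offset_s = s0)$rmse)
    }, numeric(1))
    mean(vals)
  }
  set.seed(seed)
  np <- max(6L, 2L * d)
  pop <- matrix(runif(np * d), np, d)
  pop[1, ] <- 0.5                       # midpoint as the canonical first point
  pop <- sweep(sweep(pop, 2, upper - lower, `*`), 2, lower, `+`)
  fit <- rep(Inf, np)
  evals <- 0L
  for (i in seq_len(np)) {
    if (evals >= budget) break
    fit[i] <- objective(pop[i, ])
    evals <- evals + 1L
  }
  Fw <- 0.7; CR <- 0.9
  while (evals < budget) {
    for (i in seq_len(np)) {
      if (evals >= budget) break
      r <- sample(setdiff(seq_len(np), i), 3)
      mutant <- pop[r[1], ] + Fw * (pop[r[2], ] - pop[r[3], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      jrand <- sample.int(d, 1)
      cross <- runif(d) < CR
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      f <- objective(trial)
      evals <- evals + 1L
      if (f <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- f
      }
    }
  }
  best <- which.min(fit)
  list(par = setNames(pop[best, ], nm), value = fit[best], evals = evals)
}

#' Scenario for the filter x calibration factorial experiment
#'
#' Bundles the gait configuration, the injected sensor error truth, and the
#' filter settings used by [run_factorial_experiment()].  The default truth
#' carries gain, bias and rate-dependent scale errors so that the
#' simplified protocol (which cannot observe the rate dependence) is
#' genuinely handicapped relative to the complex protocol.
#'
#' @param gait A [gait_config()].
#' @param truth A [sensor_model()] injected into the simulated sensors.
#' @param params Filter parameters, see [run_filter()].
#' @param zeta Reliability threshold, m/s^2.
#' @param rig_noise Named list of rig noise levels
#'   (`six_position`, `ninety_deg`, `turntable`, `temperature_sweep`).
#' @param pot_noise Potentiometer noise std, degrees.
#' @return A list of class `factorial_scenario`.
#' @export
factorial_scenario <- function(gait = gait_config(duration = 40,
                                                  bias_init = 0.5),
                               truth = sensor_model(
                                 accel_gain = diag(c(1.02, 0.99, 1.01)),
                                 accel_bias = c(0.1, -0.05, 0.08),
                                 gyro_gain = c(1.03, 1.04, 0.97),
                                 gyro_bias = c(0.5, 0.8, -0.6),
                                 gyro_temp_coeff = c(0.02, 0.03, 0.02),
                                 rate_scale = c(1e-4, 1.5e-4, 1.2e-4)
                               ),
                               params = list(),
                               zeta = 0.4,
                               rig_noise = list(six_position = 0.02,
                                                ninety_deg = 0.2,
                                                turntable = 0.2,
                                                temperature_sweep = 0.2),
                               pot_noise = 0.25) {
  stopifnot(inherits(gait, "gait_config"), inherits(truth, "sensor_model"))
  structure(list(gait = gait, truth = truth, params = params, zeta = zeta,
                 rig_noise = rig_noise, pot_noise = pot_noise),
            class = "factorial_scenario")
}

#' Run the filter x calibration factorial experiment on synthetic data
#'
#' For every replicate seed: simulate a walking trial and its raw digital
#' sensor data under the scenario's injected sensor errors; simulate the
#' calibration rigs and fit the simplified and complex models; apply each
#' model; run each filter from every optimization start point; score RMSE
#' and ME on the validation window from every validation start point.
#'
#' @param scenario A [factorial_scenario()].
#' @param protocol An [eval_protocol()] whose windows fit inside the
#'   scenario's trial duration.
#' @param seeds Integer vector of replicate seeds.
#' @param filters Character vector of filters to include.
#' @return A tidy data frame (`seed`, `filter`, `calibration`, `start_opt`,
#'   `start_val`, `segment`, `rmse`, `me`, `update_fraction`) of class
#'   `factorial_result`.
#' @export
run_factorial_experiment <- function(scenario,
                                     protocol = eval_protocol(),
                                     seeds = 1:20,
                                     filters = c("local", "matricial",
                                                 "markovian")) {
  stopifnot(inherits(scenario, "factorial_scenario"),
            inherits(protocol, "eval_protocol"))
  rows <- list()
  for (seed in seeds) {
    cfg <- scenario$gait
    cfg$seed <- as.integer(seed)
    traj <- generate_trajectory(cfg)
    sim <- simulate_imu(traj, cfg)
    pots <- simulate_potentiometers(traj, noise_std = scenario$pot_noise,
                                    seed = seed + 7919L)
    digital <- digitize_recording(sim$recording, scenario$truth)
    rig_seed <- function(k) as.integer((seed * 131L + k) %% .Machine$integer.max)
    rigs <- list(
      six_position = simulate_rig("six_position", scenario$truth,
                                  noise = scenario$rig_noise$six_position,
                                  seed = rig_seed(1L)),
      ninety_deg = simulate_rig("ninety_deg", scenario$truth,
                                noise = scenario$rig_noise$ninety_deg,
                                seed = rig_seed(2L)),
      turntable = simulate_rig("turntable", scenario$truth,
                               noise = scenario$rig_noise$turntable,
                               seed = rig_seed(3L)),
      temperature_sweep = simulate_rig("temperature_sweep", scenario$truth,
                                       noise = scenario$rig_noise$temperature_sweep,
                                       seed = rig_seed(4L))
    )
    models <- list(
      simplified = fit_calibration(rigs, "simplified"),
      complex = fit_calibration(rigs, "complex")
    )
    for (cal in names(models)) {
      physical <- apply_calibration(digital, models[[cal]])
      for (flt in filters) {
        for (s_opt in protocol$opt_starts) {
          res <- run_filter(slice_recording(physical, s_opt),
                            pots = slice_pots(pots, s_opt),
                            filter = flt, params = scenario$params,
                            zeta = scenario$zeta)
          uf <- update_fraction(res)
          for (s_val in protocol$val_starts) {
            sc <- score_filter(res, traj,
                               window = c(s_val, protocol$val_window[2]),
                               offset_s = s_opt)
            rows[[length(rows) + 1L]] <- data.frame(
              seed = seed, filter = flt, calibration = cal,
              start_opt = s_opt, start_val = s_val,
              segment = sc$segment, rmse = sc$rmse, me = sc$me,
              update_fraction = uf
            )
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("factorial_result", class(out))
  out
}

#' Summarize a factorial experiment
#'
#' @param tbl A [run_factorial_experiment()] result.
#' @return List with `means` (mean RMSE per filter x calibration),
#'   `by_segment` (adding the segment dimension), and `paired` (per filter:
#'   replicate-level mean RMSE under each calibration, their differences,
#'   and the count of replicates in which the complex calibration is at
#'   least as good).
#' @export
summarize_factorial <- function(tbl) {
  stopifnot(inherits(tbl, "factorial_result"))
  means <- aggregate(rmse ~ filter + calibration, data = tbl, FUN = mean)
  by_segment <- aggregate(rmse ~ segment + filter + calibration, data = tbl,
                          FUN = mean)
  per_rep <- aggregate(rmse ~ seed + filter + calibration, data = tbl,
                       FUN = mean)
  paired <- lapply(split(per_rep, per_rep$filter), function(df) {
    w <- reshape(df, idvar = "seed", timevar = "calibration",
                 direction = "wide")
    diff <- w$rmse.simplified - w$rmse.complex
    list(diff = diff, n_complex_better = sum(diff >= 0), n = length(diff))
  })
  list(means = means, by_segment = by_segment, paired = paired)
}
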