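test_that("gyro integration handles constant, zero and biased input", {
  expect_equal(integrate_gyro(rep(0, 100), theta0 = 5, rate = 50),
               rep(5, 100))
  th <- integrate_gyro(rep(90, 51), theta0 = 0, rate = 50)
  expect_equal(th[51], 90, tolerance = 1e-12)
  # constant bias b: error after t seconds is b * t (analytic drift law)
  b <- 0.5
  times <- (0:500) / 50
  w_true <- 30 * cos(times)
  drift <- integrate_gyro(w_true + b, 0, 50) - integrate_gyro(w_true, 0, 50)
  expect_equal(drift, b * times, tolerance = 1e-9)
  expect_error(integrate_gyro(numeric(0), 0, 50), "empty")
})

test_that("accelerometer inclination follows the axis convention", {
  expect_equal(accel_inclination(c(0, 0, 9.81)), 0)
  expect_equal(accel_inclination(c(9.81, 0, 0)), 90)
  expect_error(accel_inclination(c(0, 0, 0)), "zero")
  # round-trip through the simulator, noise- and motion-free
  cfg <- clean_config(duration = 4)
  trial <- make_trial(cfg)
  for (s in segment_ids()) {
    incl <- accel_inclination(trial$rec$segments[[s]]$accel)
    expect_equal(incl, unname(trial$traj$angles[, s]), tolerance = 1e-9)
  }
})

test_that("reliability criterion matches its definition exhaustively", {
  expect_true(is_reliable(c(0, 0, 9.81), zeta = 1e-9))
  expect_false(is_reliable(c(0, 0, 0), zeta = 1))
  cfg <- noisy_config(duration = 5)
  trial <- make_trial(cfg)
  zeta <- 0.4
  for (s in segment_ids()) {
    a <- trial$rec$segments[[s]]$accel
    brute <- vapply(seq_len(nrow(a)), function(k) {
      abs(sqrt(sum(a[k, ]^2)) - 9.81) <= zeta
    }, logical(1))
    expect_identical(unname(is_reliable(a, zeta = zeta)), brute)
  }
})

test_that("prediction-only local filter keeps zero state and grows P", {
  model <- filter_model(1)
  st <- filter_state(model)
  traces <- numeric(50)
  for (k in 1:50) {
    st <- local_kf_step(st, NA, model)
    traces[k] <- sum(diag(st$P))
  }
  expect_equal(st$x, c(0, 0))
  expect_true(all(diff(traces) > 0))
})

test_that("an infinite-R update degenerates to the prediction", {
  model_big <- filter_model(1, sigma_meas = 1e6)   # R = 1e12
  model <- filter_model(1)
  st0 <- filter_state(model)
  st_upd <- local_kf_step(st0, 10, model_big)
  st_pred <- local_kf_step(st0, NA, model)
  expect_equal(st_upd$x, st_pred$x, tolerance = 1e-9)
  expect_equal(st_upd$P, st_pred$P, tolerance = 1e-3)
})

test_that("a single update matches the scalar Kalman closed form", {
  model <- filter_model(1, T = 0.02, tau_g = 50, sigma_g = 0.3,
                        sigma_bg = 0.07, sigma_meas = 1)
  st <- filter_state(model, sd_theta0 = 1, sd_b0 = 0.5)
  z <- 3
  out <- local_kf_step(st, z, model)
  # hand algebra: predict P- = F P0 F' + Q*T, then K = P-H'/(HP-H'+r)
  F <- matrix(c(1, 0, 0.02, 1 - 0.02 / 50), 2, 2)
  Pm <- F %*% diag(c(1, 0.25)) %*% t(F) + diag(c(0.3^2, 0.07^2)) * 0.02
  K <- Pm[, 1] / (Pm[1, 1] + 1)
  expect_equal(out$x, K * z, tolerance = 1e-12)
  expect_equal(out$x[1], Pm[1, 1] / (Pm[1, 1] + 1) * z, tolerance = 1e-12)
})

test_that("matricial update rule enforces the two-IMU minimum", {
  model <- filter_model(4)
  st0 <- filter_state(model)
  z <- c(1, 2, 3, 4)
  one <- matricial_kf_step(st0, z, c(TRUE, FALSE, FALSE, FALSE), model)
  none <- matricial_kf_step(st0, z, rep(FALSE, 4), model)
  expect_equal(one$x, none$x)
  expect_equal(one$P, none$P)
  two <- matricial_kf_step(st0, z, c(TRUE, TRUE, FALSE, FALSE), model)
  expect_false(isTRUE(all.equal(two$x, none$x)))
})

test_that("block-diagonal matricial filtering equals independent local runs", {
  model4 <- filter_model(4)
  model1 <- filter_model(1)
  st4 <- filter_state(model4)
  st1 <- replicate(4, filter_state(model1), simplify = FALSE)
  set.seed(99)
  for (k in 1:100) {
    z <- rnorm(4)
    st4 <- matricial_kf_step(st4, z, rep(TRUE, 4), model4)
    for (i in 1:4) st1[[i]] <- local_kf_step(st1[[i]], z[i], model1)
  }
  for (i in 1:4) {
    expect_equal(st4$x[c(2 * i - 1, 2 * i)], st1[[i]]$x, tolerance = 1e-9)
  }
})

test_that("zero innovation leaves the matricial state unchanged", {
  model <- filter_model(4)
  st <- filter_state(model, x0 = rep(c(2, 0.1), 4))
  pred_x <- as.numeric(model$F %*% st$x)
  z <- pred_x[c(1, 3, 5, 7)]
  out <- matricial_kf_step(st, z, rep(TRUE, 4), model)
  expect_equal(out$x, pred_x, tolerance = 1e-12)
})

test_that("markovian state selection is the argmin of norm residuals", {
  model <- filter_model(4)
  st <- filter_state(model)
  mk_accel <- function(resid) {
    t(vapply(resid, function(r) c(0, 0, 9.81 + r), numeric(3)))
  }
  out <- markovian_kf_step(st, mk_accel(c(0.5, 0.1, 0.3, 0.2)),
                           rep(0, 4), c(0, 0, 0), model)
  expect_identical(out$markov$theta, "T")
  expect_equal(out$markov$rho, 0.1)
  # ties break in the fixed order B < T < S < F
  tie <- markovian_kf_step(filter_state(model), mk_accel(c(0.2, 0.1, 0.1, 0.3)),
                           rep(0, 4), c(0, 0, 0), model)
  expect_identical(tie$markov$theta, "T")
  # reliability failure: prediction only
  far <- markovian_kf_step(filter_state(model), mk_accel(rep(5, 4)),
                           rep(0, 4), c(0, 0, 0), model, zeta = 0.4)
  expect_false(far$markov$updated)
  expect_equal(far$state$x, rep(0, 8))
})

test_that("potentiometer chaining reproduces each segment's inclination", {
  cfg <- clean_config(duration = 4)
  trial <- make_trial(cfg)
  k <- 57
  incl <- vapply(segment_ids(), function(s) {
    accel_inclination(trial$rec$segments[[s]]$accel[k, ])
  }, numeric(1))
  joints <- trial$pots$joints[k, ]
  for (anchor in 1:4) {
    cumj <- c(0, cumsum(joints))
    chained <- incl[anchor] + (cumj - cumj[anchor])
    expect_equal(unname(chained), unname(incl), tolerance = 1e-9)
  }
})

test_that("markov anchor sequence is memoryless in the frame order", {
  cfg <- noisy_config(duration = 5)
  trial <- make_trial(cfg, pot_noise = 0.25)
  res <- run_filter(trial$rec, pots = trial$pots, filter = "markovian",
                    theta0 = trial$traj$angles[1, ])
  # per-frame oracle, computed independently of the filter loop
  oracle <- vapply(seq_along(trial$rec$times), function(k) {
    r <- vapply(segment_ids(), function(s) {
      abs(sqrt(sum(trial$rec$segments[[s]]$accel[k, ]^2)) - 9.81)
    }, numeric(1))
    segment_ids()[which.min(r)]
  }, character(1))
  expect_identical(res$update_log$markov_state, oracle)
  # permuting frames permutes the anchors identically (no hidden state)
  set.seed(1)
  perm <- sample(length(oracle))
  perm_rec <- trial$rec
  for (s in segment_ids()) {
    perm_rec$segments[[s]]$accel <- perm_rec$segments[[s]]$accel[perm, ]
  }
  perm_oracle <- vapply(seq_along(perm), function(k) {
    r <- vapply(segment_ids(), function(s) {
      abs(sqrt(sum(perm_rec$segments[[s]]$accel[k, ]^2)) - 9.81)
    }, numeric(1))
    segment_ids()[which.min(r)]
  }, character(1))
  expect_identical(perm_oracle, oracle[perm])
})

test_that("noise-free trials are tracked to integration tolerance", {
  cfg <- clean_config(duration = 10, motion_amp = c(B = 2.5, T = 2.5,
                                                    S = 3, F = 4))
  trial <- make_trial(cfg)
  for (f in c("local", "matricial", "markovian")) {
    res <- run_filter(trial$rec, pots = trial$pots, filter = f,
                      theta0 = trial$traj$angles[1, ])
    expect_lt(max(score_filter(res, trial$traj)$rmse), 0.2)
  }
})

test_that("with no reliable frames the estimate is the drifting integral", {
  cfg <- noisy_config(duration = 5)
  trial <- make_trial(cfg)
  res <- run_filter(trial$rec, filter = "local",
                    theta0 = trial$traj$angles[1, ], zeta = 0)
  expect_equal(sum(res$updates), 0)
  expect_equal(res$est$angles, res$gyro$angles)
  # and the drift makes it strictly worse than the corrected filters
  drift_rmse <- mean(score_filter(res, trial$traj)$rmse)
  corr <- run_filter(trial$rec, filter = "local",
                     theta0 = trial$traj$angles[1, ], zeta = 0.4)
  expect_lt(mean(score_filter(corr, trial$traj)$rmse), drift_rmse)
})

test_that("update log counts agree with the brute-force criterion counts", {
  cfg <- noisy_config(duration = 5)
  trial <- make_trial(cfg, pot_noise = 0.25)
  zeta <- 0.4
  resid <- vapply(segment_ids(), function(s) {
    abs(sqrt(rowSums(trial$rec$segments[[s]]$accel^2)) - 9.81)
  }, numeric(length(trial$rec$times)))
  loc <- run_filter(trial$rec, filter = "local",
                    theta0 = trial$traj$angles[1, ], zeta = zeta)
  expect_identical(unname(colSums(loc$updates)),
                   unname(colSums(resid <= zeta)))
  mat <- run_filter(trial$rec, filter = "matricial",
                    theta0 = trial$traj$angles[1, ], zeta = zeta)
  expect_identical(sum(mat$update_log$updated),
                   sum(rowSums(resid <= zeta) >= 2))
  mrk <- run_filter(trial$rec, pots = trial$pots, filter = "markovian",
                    theta0 = trial$traj$angles[1, ], zeta = zeta)
  expect_identical(sum(mrk$update_log$updated),
                   sum(apply(resid, 1, min) <= zeta))
})

test_that("cooperative filters beat the local filter on the trunk under a
           degraded calibration", {
  wins_mat <- wins_mrk <- 0
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    cfg <- gait_config(duration = 10, bias_init = 0.5, seed = seed)
    trial <- make_trial(cfg, pot_noise = 0.25)
    rec <- trial$rec
    for (s in segment_ids()) {       # injected 2 percent gyro scale error
      rec$segments[[s]]$gyro <- rec$segments[[s]]$gyro * 1.02
    }
    th0 <- trial$traj$angles[1, ]
    rm <- function(f) {
      res <- run_filter(rec, pots = trial$pots, filter = f, theta0 = th0)
      score_filter(res, trial$traj)$rmse[1]   # trunk
    }
    r_loc <- rm("local")
    if (rm("matricial") <= r_loc) wins_mat <- wins_mat + 1
    if (rm("markovian") <= r_loc) wins_mrk <- wins_mrk + 1
  }
  expect_gt(wins_mat, n_rep / 2)
  expect_gt(wins_mrk, n_rep / 2)
})

test_that("non-positive-semidefinite covariances are rejected", {
  model <- filter_model(1)
  st <- filter_state(model)
  st$P <- matrix(c(-1, 0, 0, 1), 2, 2)
  expect_error(local_kf_step(st, NA, model), "positive semi-definite")
  st$P <- matrix(c(1, 0.5, 0, 1), 2, 2)
  expect_error(local_kf_step(st, NA, model), "symmetric")
})

test_that("running a digital recording requires and uses a calibration", {
  cfg <- noisy_config(duration = 2)
  trial <- make_trial(cfg)
  truth <- example_truth()
  dig <- digitize_recording(trial$rec, truth)
  expect_error(run_filter(dig, filter = "local"), "calibration")
  res <- run_filter(dig, filter = "local", calibration = truth,
                    theta0 = trial$traj$angles[1, ])
  ref <- run_filter(trial$rec, filter = "local",
                    theta0 = trial$traj$angles[1, ])
  expect_equal(res$est$angles, ref$est$angles, tolerance = 1e-6)
  expect_error(run_filter(trial$rec, filter = "markovian"), "potentiometer")
})
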