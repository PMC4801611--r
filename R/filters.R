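# Error-state Kalman filters for absolute segment angle estimation.
#
# Per segment the filter state is x = (delta_theta, delta_b): the correction
# to the gyro-integrated angle and the (negated) gyro bias, with continuous
# dynamics  d/dt [dtheta; db] = [[0,1],[0,-1/tau_g]] [dtheta; db] + w  and
# angle-only output  z = [1, 0] x + v.  Discretization: F = I + A*T,
# G = B*sqrt(T) (so the discrete process noise is Q*T), H = C.
# The fused estimate is theta_hat = theta_gyro + delta_theta_hat.
#
# Three filters share this model:
#   local     — four independent 2-state filters, each updated only when its
#               own accelerometer passes the reliability criterion;
#   matricial — one filter over the stacked 8-state vector; updates use the
#               rows of the stacked output matrix belonging to reliable
#               segments and require at least two reliable IMUs;
#   markovian — a Markov jump filter: each frame the most reliable IMU
#               (smallest | ||a|| - g | ) anchors the measurement and the
#               exoskeleton potentiometer joint angles chain its inclination
#               to every other segment.

#' Build the discrete filter model matrices
#'
#' @param n_segments Number of stacked segments (1 for a local filter,
#'   4 for the cooperative filters).
#' @param T Sampling period, seconds.
#' @param tau_g Gauss-Markov correlation time of the gyro bias, seconds
#'   (scalar or per segment).
#' @param sigma_g Gyroscope white-noise density driving the angle error,
#'   deg/s (scalar or per segment).
#' @param sigma_bg Driving-noise density of the bias state, deg/s/sqrt(s)
#'   (scalar or per segment).
#' @param sigma_meas Accelerometer-inclination measurement noise, degrees
#'   (scalar or per segment).  This is the angle-domain counterpart of the
#'   accelerometer noise: roughly `(sigma_a / g) * 180 / pi` plus a margin
#'   for motion acceleration leaking through the reliability gate.
#' @param sigma_pot Potentiometer joint-angle noise, degrees (Markovian
#'   filter only).
#' @return An object of class `filter_model` holding `F`, `Qd` (discrete
#'   process noise `Q * T`), `H`, `R` and bookkeeping.
#' @export
filter_model <- function(n_segments = 4, T = 1 / 50, tau_g = 50,
                         sigma_g = 0.3, sigma_bg = 0.07,
                         sigma_meas = 1, sigma_pot = 0.25) {
  n <- n_segments
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else {
    stopifnot(length(x) == n); as.numeric(x)
  }
  tau_g <- rep_n(tau_g); sigma_g <- rep_n(sigma_g)
  sigma_bg <- rep_n(sigma_bg); sigma_meas <- rep_n(sigma_meas)
  if (any(tau_g <= 0)) stop("tau_g must be > 0", call. = FALSE)
  F <- matrix(0, 2 * n, 2 * n)
  H <- matrix(0, n, 2 * n)
  q <- numeric(2 * n)
  for (i in seq_len(n)) {
    r <- 2 * i - 1
    F[r, r] <- 1; F[r, r + 1] <- T
    F[r + 1, r + 1] <- 1 - T / tau_g[i]
    H[i, r] <- 1
    q[r] <- sigma_g[i]^2
    q[r + 1] <- sigma_bg[i]^2
  }
  structure(
    list(F = F, Qd = diag(q * T, 2 * n), H = H,
         R = diag(sigma_meas^2, n), T = T, n = n, tau_g = tau_g,
         sigma_meas = sigma_meas, sigma_pot = sigma_pot),
    class = "filter_model"
  )
}

#' Initialize a filter state
#'
#' @param model A [filter_model()].
#' @param x0 Initial stacked state (defaults to zero: the gyro-integrated
#'   angle is trusted at start-up).
#' @param sd_theta0,sd_b0 Initial standard deviations of the angle and bias
#'   errors (degrees, deg/s) forming the diagonal initial covariance.
#' @return An object of class `filter_state` with `x`, `P` and step counter
#'   `k`.
#' @export
filter_state <- function(model, x0 = NULL, sd_theta0 = 1, sd_b0 = 0.5) {
  n <- model$n
  if (is.null(x0)) x0 <- numeric(2 * n)
  stopifnot(length(x0) == 2 * n)
  P <- diag(rep(c(sd_theta0^2, sd_b0^2), n), 2 * n)
  structure(list(x = as.numeric(x0), P = P, k = 0L), class = "filter_state")
}

# internal: symmetrize the covariance (round-off control)
sym <- function(P) (P + t(P)) / 2

check_state <- function(state) {
  if (!inherits(state, "filter_state")) stop("not a filter_state", call. = FALSE)
  if (max(abs(state$P - t(state$P))) > 1e-9) {
    stop("state covariance is not symmetric", call. = FALSE)
  }
  ev <- eigen(state$P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) {
    stop("state covariance is not positive semi-definite", call. = FALSE)
  }
  invisible(state)
}

# internal prediction: x <- F x, P <- F P F' + Q*T
kf_predict_ <- function(state, model) {
  state$x <- as.numeric(model$F %*% state$x)
  state$P <- sym(model$F %*% state$P %*% t(model$F) + model$Qd)
  state$k <- state$k + 1L
  state
}

# internal measurement update on a subset of output rows (Joseph form)
kf_update_ <- function(state, z, rows, model, R = NULL) {
  H <- model$H[rows, , drop = FALSE]
  if (is.null(R)) R <- model$R[rows, rows, drop = FALSE]
  S <- H %*% state$P %*% t(H) + R
  K <- state$P %*% t(H) %*% solve(S)
  state$x <- state$x + as.numeric(K %*% (z - H %*% state$x))
  IKH <- diag(nrow(state$P)) - K %*% H
  state$P <- sym(IKH %*% state$P %*% t(IKH) + K %*% R %*% t(K))
  state
}

#' One step of the local Kalman filter (single segment)
#'
#' Performs the prediction and, when a reliable accelerometer measurement is
#' available, the update.  The measurement is the accelerometer inclination
#' minus the gyro-integrated angle, i.e. an observation of the angle
#' correction; pass `NA` when the reliability criterion fails so that only
#' the prediction is performed.
#'
#' @param state A single-segment [filter_state()].
#' @param z Scalar measurement in degrees, or `NA` for prediction only.
#' @param model A single-segment [filter_model()].
#' @return The updated `filter_state`.
#' @export
local_kf_step <- function(state, z, model) {
  stopifnot(model$n == 1)
  check_state(state)
  state <- kf_predict_(state, model)
  if (!is.na(z)) state <- kf_update_(state, z, 1L, model)
  state
}

#' One step of the cooperative matricial Kalman filter
#'
#' Predicts the stacked four-segment state; an update is performed only when
#' at least `min_reliable` segments pass the accelerometer reliability
#' criterion, using the rows of the stacked output matrix (and of `R`)
#' belonging to those segments.  Cross-segment corrections arise through the
#' off-diagonal covariance terms.
#'
#' @param state A four-segment [filter_state()].
#' @param z Length-4 measurement vector (inclination minus gyro-integrated
#'   angle per segment, degrees); entries for unreliable segments are
#'   ignored.
#' @param mask Logical length-4 reliability mask.
#' @param model A four-segment [filter_model()].
#' @param min_reliable Minimum number of reliable IMUs required for an
#'   update (default 2).
#' @return The updated `filter_state`.
#' @export
matricial_kf_step <- function(state, z, mask, model, min_reliable = 2) {
  stopifnot(model$n == length(mask), length(z) == length(mask))
  check_state(state)
  state <- kf_predict_(state, model)
  rows <- which(mask)
  if (length(rows) >= min_reliable) {
    state <- kf_update_(state, z[rows], rows, model)
  }
  state
}

#' One step of the cooperative Markovian (jump) Kalman filter
#'
#' Selects the most reliable IMU of the frame,
#' `Theta = argmin_i | ||a_i|| - g |` (ties broken in the fixed order B, T,
#' S, F), with reliability index `rho = min_i | ||a_i|| - g |`.  If `rho`
#' fails the criterion only the prediction runs.  Otherwise the measurement
#' vector anchors every segment to Theta's accelerometer inclination chained
#' through the potentiometer joint angles; the measurement covariance of a
#' non-anchor segment is inflated by the potentiometer noise once per joint
#' crossed.  The switch of anchor between frames depends only on the current
#' frame — the Markovian jump.
#'
#' @param state A four-segment [filter_state()].
#' @param accel 4x3 matrix of accelerometer vectors (rows B, T, S, F),
#'   m/s^2.
#' @param theta_g Length-4 gyro-integrated angles at this frame, degrees.
#' @param joints Length-3 potentiometer joint angles (hip, knee, ankle) at
#'   this frame, degrees.
#' @param model A four-segment [filter_model()].
#' @param zeta Reliability threshold, m/s^2.
#' @param g_mag Gravity magnitude, m/s^2.
#' @return List with `state` (updated `filter_state`) and `markov` (list
#'   `theta` = anchor segment id, `rho` = reliability residual in m/s^2,
#'   `updated` = whether an update ran).
#' @export
markovian_kf_step <- function(state, accel, theta_g, joints, model,
                              zeta = 0.4, g_mag = gravity_default()) {
  stopifnot(model$n == 4, nrow(accel) == 4, length(theta_g) == 4,
            length(joints) == 3)
  check_state(state)
  state <- kf_predict_(state, model)
  resid <- abs(sqrt(rowSums(accel^2)) - g_mag)
  anchor <- which.min(resid)              # first minimum: tie order B<T<S<F
  rho <- resid[anchor]
  updated <- rho <= zeta
  if (updated) {
    incl <- accel_inclination(accel[anchor, ])
    cumj <- c(0, cumsum(joints))          # offset of each segment from B
    chained <- incl + (cumj - cumj[anchor])
    z <- chained - theta_g
    hops <- abs(seq_len(4) - anchor)
    R <- diag(model$sigma_meas^2 + hops * model$sigma_pot^2, 4)
    state <- kf_update_(state, z, 1:4, model, R = R)
  }
  list(state = state,
       markov = list(theta = segment_ids()[anchor], rho = rho,
                     updated = updated))
}

# Measurement primitives ------------------------------------------------------

#' Integrate angular velocity to an absolute angle
#'
#' Trapezoidal cumulative integration from the initial angle.  With a biased
#' gyroscope the result drifts; the Kalman filters estimate and remove that
#' drift.
#'
#' @param omega Angular velocity samples, deg/s (uniformly sampled).
#' @param theta0 Initial angle, degrees.
#' @param rate Sampling rate, Hz.
#' @return Numeric vector of angles, degrees.
#' @export
integrate_gyro <- function(omega, theta0 = 0, rate) {
  if (length(omega) == 0) stop("empty angular-velocity series", call. = FALSE)
  times <- (seq_along(omega) - 1) / rate
  theta0 + as.numeric(pracma::cumtrapz(times, omega))
}

#' Accelerometer inclination
#'
#' Sagittal inclination from a (quasi-static) accelerometer vector under the
#' module convention that gravity lies along sensor +Z at zero inclination
#' and the sagittal rotation is about sensor Y: `atan2(a_x, a_z)` in
#' degrees.
#'
#' @param accel A 3-vector, or an n x 3 matrix of accelerometer samples,
#'   m/s^2.
#' @return Inclination(s) in degrees.
#' @export
accel_inclination <- function(accel) {
  if (is.matrix(accel)) {
    if (any(rowSums(accel^2) == 0)) {
      stop("inclination undefined for a zero acceleration vector", call. = FALSE)
    }
    return(atan2(accel[, 1], accel[, 3]) * 180 / pi)
  }
  if (sum(accel^2) == 0) {
    stop("inclination undefined for a zero acceleration vector", call. = FALSE)
  }
  atan2(accel[1], accel[3]) * 180 / pi
}

#' Accelerometer reliability criterion
#'
#' A frame is reliable — usable as an inclinometer — when the norm of the
#' measured acceleration is within `zeta` of gravity:
#' `| ||a|| - g | <= zeta`.
#'
#' @param accel A 3-vector or n x 3 matrix, m/s^2.
#' @param g_mag Gravity magnitude, m/s^2.
#' @param zeta Threshold, m/s^2 (default 0.4).
#' @return Logical (vector).
#' @export
is_reliable <- function(accel, g_mag = gravity_default(), zeta = 0.4) {
  nrm <- if (is.matrix(accel)) sqrt(rowSums(accel^2)) else sqrt(sum(accel^2))
  abs(nrm - g_mag) <= zeta
}

# Trial-level driver -----------------------------------------------------------

#' Run a filter over a full trial
#'
#' Computes the gyro-integrated angle per segment, gates accelerometer
#' frames with the reliability criterion, runs the requested filter, and
#' returns the fused estimates together with an update log.
#'
#' @param rec An `imu_recording`.  If in digital units, `calibration` must
#'   be supplied and is applied first.
#' @param pots A `pot_series` (required for the Markovian filter).
#' @param filter One of `"local"`, `"matricial"`, `"markovian"`,
#'   `"gyro"` (integration only, no correction) or `"accel"` (inclination
#'   only).
#' @param params Named list of filter parameters passed to [filter_model()]:
#'   `tau_g`, `sigma_g`, `sigma_bg`, `sigma_meas`, `sigma_pot`.
#' @param calibration A [sensor_model()] (only used for digital input).
#' @param theta0 Named per-segment initial angles, degrees; default: the
#'   accelerometer inclination of the first sample (the accelerometer
#'   provides the initial orientation).
#' @param zeta Reliability threshold, m/s^2.
#' @param g_mag Gravity magnitude, m/s^2.
#' @param sd_theta0,sd_b0 Initial state standard deviations, see
#'   [filter_state()].
#' @param diagnostics If `TRUE`, record the minimum covariance eigenvalue
#'   and maximum asymmetry at every step (slower).
#' @return An object of class `kf_result`: `est` and `gyro`
#'   ([segment_angle_series()] of fused and integration-only estimates),
#'   `update_log` (data frame with per-frame update flags, reliable count,
#'   Markov state), `updates` (frames x segments logical matrix),
#'   `filter`, and optionally `diagnostics`.
#' @export
run_filter <- function(rec, pots = NULL,
                       filter = c("local", "matricial", "markovian",
                                  "gyro", "accel"),
                       params = list(), calibration = NULL, theta0 = NULL,
                       zeta = 0.4, g_mag = gravity_default(),
                       sd_theta0 = 1, sd_b0 = 0.5, diagnostics = FALSE) {
  filter <- match.arg(filter)
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$units == "digital") {
    if (is.null(calibration)) {
      stop("digital recording requires a calibration model", call. = FALSE)
    }
    rec <- apply_calibration(rec, calibration)
  }
  if (filter == "markovian" && is.null(pots)) {
    stop("the Markovian filter requires potentiometer data", call. = FALSE)
  }
  segs <- segment_ids()
  n <- length(rec$times)
  T <- 1 / rec$rate

  accel <- lapply(rec$segments[segs], `[[`, "accel")
  incl <- vapply(segs, function(s) accel_inclination(accel[[s]]),
                 numeric(n))
  resid <- vapply(segs, function(s) {
    abs(sqrt(rowSums(accel[[s]]^2)) - g_mag)
  }, numeric(n))
  reliable <- resid <= zeta

  if (is.null(theta0)) {
    theta0 <- setNames(incl[1, ], segs)
  } else if (is.null(names(theta0))) {
    theta0 <- setNames(rep_len(theta0, 4), segs)
  }
  theta_g <- vapply(segs, function(s) {
    integrate_gyro(rec$segments[[s]]$gyro[, "y"], theta0[[s]], rec$rate)
  }, numeric(n))

  if (max(abs(theta_g)) > 175) {
    warning("gyro-integrated angle left the sagittal envelope; ",
            "estimates may be unreliable")
  }

  delta <- matrix(0, n, 4, dimnames = list(NULL, segs))
  updates <- matrix(FALSE, n, 4, dimnames = list(NULL, segs))
  markov_state <- rep(NA_character_, n)
  markov_rho <- rep(NA_real_, n)
  diag_df <- if (diagnostics) {
    data.frame(min_eig = numeric(0), max_asym = numeric(0))
  } else NULL
  min_eigs <- max_asyms <- if (diagnostics) numeric(n) else NULL

  fp <- function(nm, default) if (!is.null(params[[nm]])) params[[nm]] else default
  mk_model <- function(nseg) {
    filter_model(nseg, T = T, tau_g = fp("tau_g", 50),
                 sigma_g = fp("sigma_g", 0.3), sigma_bg = fp("sigma_bg", 0.07),
                 sigma_meas = fp("sigma_meas", 1),
                 sigma_pot = fp("sigma_pot", 0.25))
  }
  record_diag <- function(P, k) {
    if (!diagnostics) return()
    min_eigs[k] <<- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
    max_asyms[k] <<- max(abs(P - t(P)))
  }

  if (filter == "gyro") {
    # no correction
  } else if (filter == "accel") {
    delta <- incl - theta_g
  } else if (filter == "local") {
    model1 <- mk_model(1)
    for (s in segs) {
      st <- filter_state(model1, sd_theta0 = sd_theta0, sd_b0 = sd_b0)
      j <- segment_index(s)
      for (k in seq_len(n)) {
        st <- kf_predict_(st, model1)
        if (reliable[k, j]) {
          st <- kf_update_(st, incl[k, j] - theta_g[k, j], 1L, model1)
          updates[k, j] <- TRUE
        }
        delta[k, j] <- st$x[1]
        if (s == "B") record_diag(st$P, k)
      }
    }
  } else if (filter == "matricial") {
    model4 <- mk_model(4)
    st <- filter_state(model4, sd_theta0 = sd_theta0, sd_b0 = sd_b0)
    for (k in seq_len(n)) {
      st <- kf_predict_(st, model4)
      rows <- which(reliable[k, ])
      if (length(rows) >= 2) {
        st <- kf_update_(st, incl[k, rows] - theta_g[k, rows], rows, model4)
        updates[k, rows] <- TRUE
      }
      delta[k, ] <- st$x[c(1, 3, 5, 7)]
      record_diag(st$P, k)
    }
  } else { # markovian
    model4 <- mk_model(4)
    st <- filter_state(model4, sd_theta0 = sd_theta0, sd_b0 = sd_b0)
    for (k in seq_len(n)) {
      st <- kf_predict_(st, model4)
      anchor <- which.min(resid[k, ])
      rho <- resid[k, anchor]
      markov_state[k] <- segs[anchor]
      markov_rho[k] <- rho
      if (rho <= zeta) {
        cumj <- c(0, cumsum(pots$joints[k, ]))
        chained <- incl[k, anchor] + (cumj - cumj[anchor])
        z <- chained - theta_g[k, ]
        hops <- abs(seq_len(4) - anchor)
        R <- diag(model4$sigma_meas^2 + hops * model4$sigma_pot^2, 4)
        st <- kf_update_(st, z, 1:4, model4, R = R)
        updates[k, ] <- TRUE
      }
      delta[k, ] <- st$x[c(1, 3, 5, 7)]
      record_diag(st$P, k)
    }
  }

  theta_hat <- theta_g + delta
  log <- data.frame(
    time_s = rec$times,
    updated = rowSums(updates) > 0,
    n_reliable = rowSums(reliable),
    markov_state = markov_state,
    markov_rho = markov_rho
  )
  out <- list(
    est = segment_angle_series(rec$times, theta_hat, rec$rate),
    gyro = segment_angle_series(rec$times, theta_g, rec$rate),
    update_log = log, updates = updates, reliable = reliable,
    filter = filter, zeta = zeta
  )
  if (diagnostics) {
    out$diagnostics <- data.frame(min_eig = min_eigs, max_asym = max_asyms)
  }
  class(out) <- "kf_result"
  out
}

#' @export
print.kf_result <- function(x, ...) {
  cat(sprintf("<kf_result> filter=%s, %d frames, update fraction %.3f\n",
              x$filter, nrow(x$update_log), update_fraction(x)))
  invisible(x)
}

#' Fraction of the trial in which accelerometer updates were performed
#'
#' For the local filter this is the mean of the per-segment update
#' fractions; for the cooperative filters it is the fraction of frames with
#' an update.
#'
#' @param result A [run_filter()] result.
#' @return A number in `[0, 1]`.
#' @export
update_fraction <- function(result) {
  stopifnot(inherits(result, "kf_result"))
  if (result$filter == "local") {
    mean(colMeans(result$updates))
  } else {
    mean(result$update_log$updated)
  }
}
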