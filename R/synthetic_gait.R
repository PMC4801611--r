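# Synthetic gait trajectories and sensor simulation.
#
# The simulator stands in for the motion-capture reference and instrumented
# calibration rigs: it produces ground-truth sagittal segment angles for
# trunk/thigh/shank/foot, raw IMU signals (gyroscope with Gauss-Markov bias
# drift, accelerometer with gravity + gated motion acceleration), exoskeleton
# potentiometer joint angles, and bench recordings for every calibration
# protocol.  All generators are deterministic given a seed.

#' Configuration for the synthetic gait and sensor simulator
#'
#' Angles are in degrees, rates in deg/s, accelerations in m/s^2.  Each
#' segment's angle is a Fourier series (offset + sum of sinusoids at the
#' gait fundamental and its harmonics).  Motion acceleration — the body
#' acceleration that corrupts the accelerometer as an inclinometer — is
#' gated off during a quasi-static dwell window in each gait cycle; the
#' trunk has the smallest dwell fraction because it is the segment with the
#' fewest quasi-static moments.
#'
#' @param rate Sampling rate in Hz.
#' @param duration Trial duration in seconds; `duration * rate` must be a
#'   whole number of samples.
#' @param cycle_freq Gait cycle fundamental frequency in Hz (default one
#'   cycle per 1.1 s, a slow treadmill cadence).
#' @param offsets Named per-segment constant angle, degrees.
#' @param amplitudes Named per-segment fundamental amplitude, degrees.
#'   Defaults (trunk 3, thigh 25, shank 35, foot 20) are plausible
#'   slow-walking magnitudes, configurable and not a reproduction of any
#'   subject.
#' @param harmonic_frac Amplitude of the second harmonic relative to the
#'   fundamental (adds gait-like asymmetry).
#' @param phases Named per-segment phase of the fundamental, radians.
#' @param dwell Named per-segment quasi-static fraction of each gait cycle
#'   during which motion acceleration is zero; trunk smallest.
#' @param motion_amp Named per-segment motion-acceleration amplitude, m/s^2.
#' @param bias_init Initial gyroscope bias, deg/s (scalar or named per
#'   segment).
#' @param tau_g Correlation time of the first-order Gauss-Markov gyro bias
#'   process, seconds.
#' @param sigma_g Gyroscope white-noise standard deviation, deg/s.
#' @param sigma_b Per-step driving noise of the bias process, deg/s.
#' @param sigma_a Accelerometer white-noise standard deviation, m/s^2.
#' @param temp_c Sensor temperature during the trial, Celsius.
#' @param seed Integer seed controlling every random draw.
#'
#' @return An object of class `gait_config` (a validated list).
#' @export
#' @examples
#' cfg <- gait_config(duration = 10)
#' traj <- generate_trajectory(cfg)
#' range(traj$angles[, "T"])
gait_config <- function(rate = 50,
                        duration = 60,
                        cycle_freq = 1 / 1.1,
                        offsets = c(B = 2, T = 5, S = -10, F = 0),
                        amplitudes = c(B = 3, T = 25, S = 35, F = 20),
                        harmonic_frac = 0.2,
                        phases = c(B = 0.4, T = 0, S = -1.2, F = -2.1),
                        dwell = c(B = 0.15, T = 0.30, S = 0.30, F = 0.35),
                        motion_amp = c(B = 2.5, T = 2.5, S = 3.0, F = 4.0),
                        bias_init = 0.3,
                        tau_g = 50,
                        sigma_g = 0.3,
                        sigma_b = 0.01,
                        sigma_a = 0.05,
                        temp_c = 25,
                        seed = 1L) {
  if (!is.numeric(rate) || rate <= 0) {
    stop("`rate` must be a positive number of Hz", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive seconds", call. = FALSE)
  }
  n <- duration * rate
  if (abs(n - round(n)) > 1e-9) {
    stop("`duration * rate` must be an integer sample count", call. = FALSE)
  }
  if (tau_g <= 0) stop("`tau_g` must be > 0", call. = FALSE)
  if (any(c(sigma_g, sigma_b, sigma_a) < 0)) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  segs <- segment_ids()
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, 4), segs)
    if (!all(segs %in% names(x))) {
      stop("per-segment parameter must name all of B, T, S, F", call. = FALSE)
    }
    x[segs]
  }
  cfg <- list(
    rate = rate, duration = duration, n = as.integer(round(n)),
    cycle_freq = cycle_freq,
    offsets = expand(offsets), amplitudes = expand(amplitudes),
    harmonic_frac = harmonic_frac, phases = expand(phases),
    dwell = expand(dwell), motion_amp = expand(motion_amp),
    bias_init = expand(bias_init), tau_g = tau_g,
    sigma_g = sigma_g, sigma_b = sigma_b, sigma_a = sigma_a,
    temp_c = temp_c, seed = as.integer(seed)
  )
  class(cfg) <- "gait_config"
  cfg
}

#' Construct a segment-angle time series
#'
#' Container for ground-truth or estimated absolute sagittal angles of the
#' four segments on a shared uniform time base.
#'
#' @param times Sample times in seconds, strictly increasing, uniform step.
#' @param angles Numeric matrix, one column per segment (B, T, S, F), degrees.
#' @param rate Sampling rate, Hz.
#' @return An object of class `segment_angle_series`.
#' @export
segment_angle_series <- function(times, angles, rate) {
  angles <- as.matrix(angles)
  if (is.null(colnames(angles))) colnames(angles) <- segment_ids()[seq_len(ncol(angles))]
  stopifnot(length(times) == nrow(angles))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
    if (max(abs(dt - 1 / rate)) > 1e-6) {
      stop("times must be uniform with step 1/rate", call. = FALSE)
    }
  }
  if (!all(is.finite(angles))) stop("angles must be finite", call. = FALSE)
  structure(list(times = times, angles = angles, rate = rate),
            class = "segment_angle_series")
}

#' @export
print.segment_angle_series <- function(x, ...) {
  cat(sprintf("<segment_angle_series> %d samples @ %g Hz, segments: %s\n",
              length(x$times), x$rate, paste(colnames(x$angles), collapse = ", ")))
  invisible(x)
}

#' Generate a ground-truth walking trajectory
#'
#' Each segment's absolute sagittal angle is a deterministic Fourier series:
#' offset + fundamental + one second harmonic.  Serves as the reference
#' against which sensor-fusion estimates are scored.
#'
#' @param config A [gait_config()].
#' @return A [segment_angle_series()] with one column per segment.
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  times <- (seq_len(config$n) - 1) / config$rate
  f0 <- config$cycle_freq
  angles <- vapply(segment_ids(), function(s) {
    a <- config$amplitudes[[s]]
    ph <- config$phases[[s]]
    config$offsets[[s]] +
      a * sin(2 * pi * f0 * times + ph) +
      a * config$harmonic_frac * sin(2 * pi * 2 * f0 * times + 2 * ph + 0.5)
  }, numeric(length(times)))
  if (max(abs(angles)) > 120) {
    stop("configured gait exceeds the +/-120 degree sagittal envelope",
         call. = FALSE)
  }
  out <- segment_angle_series(times, angles, config$rate)
  # analytic angular velocity (deg/s), used by simulate_imu so the gyro
  # carries the true rate rather than a finite-difference approximation
  attr(out, "velocity") <- vapply(segment_ids(), function(s) {
    a <- config$amplitudes[[s]]
    ph <- config$phases[[s]]
    a * 2 * pi * f0 * cos(2 * pi * f0 * times + ph) +
      a * config$harmonic_frac * 4 * pi * f0 *
        cos(2 * pi * 2 * f0 * times + 2 * ph + 0.5)
  }, numeric(length(times)))
  out
}

# internal: motion-acceleration waveform in [-1, 1] scaled by amplitude.
# Zero during the quasi-static dwell window of each cycle, a smooth bump
# modulated at twice the gait frequency outside it.
motion_profile <- function(times, f0, dwell, phase) {
  p <- (times * f0 + phase / (2 * pi)) %% 1
  gate <- ifelse(p < dwell, 0, sin(pi * (p - dwell) / (1 - dwell))^2)
  gate * sin(2 * pi * 2 * f0 * times + phase)
}

# Fraction of the motion acceleration leaking tangentially (sensor X),
# corrupting the inclination reading during movement; the rest acts along
# the gravity direction and perturbs the acceleration norm.
MOTION_TANGENTIAL_FRAC <- 0.3

#' Simulate IMU recordings from a ground-truth trajectory
#'
#' Gyroscope model (sagittal axis = sensor Y):
#' `gyro_y = dtheta/dt + b(t) + eta_g`, with the bias `b` a first-order
#' Gauss-Markov process `b[k+1] = (1 - T/tau_g) * b[k] + eta_b` discretized
#' by forward Euler.  Accelerometer model: gravity rotated into the sensor
#' frame by the segment angle (at theta = 0 gravity lies along sensor +Z;
#' sagittal rotation is about sensor Y, so inclination = atan2(a_x, a_z)),
#' plus a motion-acceleration term scaled by the per-segment amplitude and
#' gated by the quasi-static dwell, plus white noise.  The motion term acts
#' mostly along the gravity direction (perturbing the acceleration norm and
#' hence the reliability criterion) with a 30 percent tangential leakage
#' along sensor X that corrupts the inclination during movement.
#'
#' @param traj A [segment_angle_series()], normally from
#'   [generate_trajectory()], whose attached analytic angular velocity is
#'   used directly; hand-built trajectories are differentiated by central
#'   differences instead.
#' @param config The [gait_config()] providing noise, bias and dwell
#'   parameters.
#' @param g_mag Gravity magnitude, m/s^2.
#' @return A list with elements `recording` (class `imu_recording`, physical
#'   units) and `bias_truth` (matrix of the true sagittal-axis gyro bias per
#'   segment, deg/s).
#' @export
simulate_imu <- function(traj, config, g_mag = gravity_default()) {
  stopifnot(inherits(traj, "segment_angle_series"),
            inherits(config, "gait_config"))
  times <- traj$times
  n <- length(times)
  T <- 1 / traj$rate
  phi <- 1 - T / config$tau_g
  set.seed(config$seed)
  segs <- segment_ids()
  bias_truth <- matrix(0, n, 4, dimnames = list(NULL, segs))
  segments <- setNames(vector("list", 4), segs)
  vel <- attr(traj, "velocity")
  for (s in segs) {
    theta <- traj$angles[, s]
    omega <- if (!is.null(vel)) vel[, s] else pracma::gradient(theta, T)
    b <- numeric(n)
    b[1] <- config$bias_init[[s]]
    eta_b <- rnorm(n, 0, config$sigma_b)
    for (k in seq_len(n - 1)) b[k + 1] <- phi * b[k] + eta_b[k + 1]
    bias_truth[, s] <- b
    gyro <- cbind(
      x = rnorm(n, 0, config$sigma_g),
      y = omega + b + rnorm(n, 0, config$sigma_g),
      z = rnorm(n, 0, config$sigma_g)
    )
    th <- theta * pi / 180
    m <- config$motion_amp[[s]] *
      motion_profile(times, config$cycle_freq, config$dwell[[s]],
                     config$phases[[s]])
    accel <- cbind(
      x = (g_mag + m) * sin(th) + MOTION_TANGENTIAL_FRAC * m +
        rnorm(n, 0, config$sigma_a),
      y = rnorm(n, 0, config$sigma_a),
      z = (g_mag + m) * cos(th) + rnorm(n, 0, config$sigma_a)
    )
    segments[[s]] <- list(accel = accel, gyro = gyro)
  }
  rec <- structure(
    list(times = times, rate = traj$rate, segments = segments,
         temperature = rep(config$temp_c, n), units = "physical"),
    class = "imu_recording"
  )
  list(recording = rec, bias_truth = bias_truth)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz, %s units, segments: %s\n",
              length(x$times), x$rate, x$units,
              paste(names(x$segments), collapse = ", ")))
  invisible(x)
}

#' Simulate exoskeleton potentiometer joint angles
#'
#' Joint angles are successive differences of the absolute segment angles
#' (`hip = theta_T - theta_B`, `knee = theta_S - theta_T`,
#' `ankle = theta_F - theta_S`) plus additive Gaussian noise.  Noise-free,
#' chaining the joint angles from any segment's absolute angle reconstructs
#' every other segment's absolute angle exactly.
#'
#' @param traj A [segment_angle_series()].
#' @param noise_std Joint-angle noise standard deviation in degrees.  The
#'   default 0.25 reflects a potentiometer linearity of 0.25 percent over a
#'   roughly 100-degree joint range.
#' @param seed Integer seed.
#' @return An object of class `pot_series` with a `joints` matrix
#'   (columns hip, knee, ankle, degrees).
#' @export
simulate_potentiometers <- function(traj, noise_std = 0.25, seed = 1L) {
  stopifnot(inherits(traj, "segment_angle_series"))
  n <- length(traj$times)
  set.seed(seed)
  a <- traj$angles
  joints <- cbind(
    hip   = a[, "T"] - a[, "B"] + rnorm(n, 0, noise_std),
    knee  = a[, "S"] - a[, "T"] + rnorm(n, 0, noise_std),
    ankle = a[, "F"] - a[, "S"] + rnorm(n, 0, noise_std)
  )
  structure(list(times = traj$times, rate = traj$rate, joints = joints),
            class = "pot_series")
}

#' @export
print.pot_series <- function(x, ...) {
  cat(sprintf("<pot_series> %d samples @ %g Hz (hip, knee, ankle)\n",
              length(x$times), x$rate))
  invisible(x)
}

# Calibration-rig simulation --------------------------------------------------

#' Construct a linear sensor (error) model
#'
#' The same structure serves as the injected ground truth of a simulated
#' sensor and as the fitted calibration model: a linear map between physical
#' quantities and raw digital readings.  Forward (physical to digital, see
#' [digitize_recording()]):
#' `accel_d = accel_gain %*% a + accel_bias`;
#' `gyro_d  = gyro_gain * (1 + rate_scale * |w|) * w + gyro_bias +
#'  gyro_temp_coeff * (temp - ref_temp_c)`.
#' The inverse map is [apply_calibration()].
#'
#' @param accel_gain 3x3 accelerometer gain (counts per m/s^2).
#' @param accel_bias Accelerometer bias, counts (length 3).
#' @param gyro_gain Per-axis gyroscope gain (diagonal; counts per deg/s).
#' @param gyro_bias Gyroscope bias, counts (length 3).
#' @param gyro_temp_coeff Per-axis linear bias drift with temperature,
#'   counts per degree Celsius.
#' @param ref_temp_c Reference temperature for the drift term, Celsius.
#' @param rate_scale Per-axis linear rate dependence of the gyroscope scale,
#'   1/(deg/s).  Nonzero values model the velocity-dependent error that only
#'   the complex (turntable) calibration can estimate.
#' @param provenance One of `"truth"`, `"simplified"`, `"complex"`.
#' @param repetition Integer repetition id of the calibration run.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(accel_gain = diag(3),
                         accel_bias = c(0, 0, 0),
                         gyro_gain = c(1, 1, 1),
                         gyro_bias = c(0, 0, 0),
                         gyro_temp_coeff = c(0, 0, 0),
                         ref_temp_c = 25,
                         rate_scale = c(0, 0, 0),
                         provenance = "truth",
                         repetition = 1L) {
  accel_gain <- as.matrix(accel_gain)
  stopifnot(all(dim(accel_gain) == c(3, 3)),
            length(accel_bias) == 3, length(gyro_gain) == 3,
            length(gyro_bias) == 3, length(gyro_temp_coeff) == 3,
            length(rate_scale) == 3)
  if (abs(det(accel_gain)) < 1e-12 || any(abs(gyro_gain) < 1e-12)) {
    stop("gain must be invertible", call. = FALSE)
  }
  provenance <- match.arg(provenance, c("truth", "simplified", "complex"))
  structure(
    list(accel_gain = accel_gain, accel_bias = as.numeric(accel_bias),
         gyro_gain = as.numeric(gyro_gain), gyro_bias = as.numeric(gyro_bias),
         gyro_temp_coeff = as.numeric(gyro_temp_coeff),
         ref_temp_c = ref_temp_c, rate_scale = as.numeric(rate_scale),
         provenance = provenance, repetition = as.integer(repetition)),
    class = "sensor_model"
  )
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("<sensor_model> provenance=%s rep=%d\n", x$provenance, x$repetition))
  cat("  accel gain diag:", signif(diag(x$accel_gain), 4),
      " bias:", signif(x$accel_bias, 4), "\n")
  cat("  gyro gain:", signif(x$gyro_gain, 4),
      " bias:", signif(x$gyro_bias, 4),
      " rate-scale:", signif(x$rate_scale, 4), "\n")
  invisible(x)
}

# internal forward gyro map for one axis (physical deg/s -> digital counts)
gyro_forward <- function(w, gain, scale, bias, tc, temp, ref) {
  gain * (1 + scale * abs(w)) * w + bias + tc * (temp - ref)
}

#' Simulate a calibration-rig recording
#'
#' Produces the raw digital data a sensor with error model `truth` would
#' output on each bench protocol:
#' \describe{
#'   \item{`six_position`}{static holds with gravity along each of +X, -X,
#'     +Y, -Y, +Z, -Z (accelerometer).}
#'   \item{`ninety_deg`}{hand-rig 90-degree rotations about each axis, both
#'     directions, half-sine rate pulses with static dwells between them
#'     (gyroscope).}
#'   \item{`turntable`}{precision constant-rate sweeps about each axis at
#'     +/- 100, 200, 300, 400, 500 deg/s (gyroscope).}
#'   \item{`temperature_sweep`}{static sensor under a linear 10 to 50
#'     Celsius ramp (gyroscope offset drift).}
#' }
#'
#' @param kind Rig kind, see above.
#' @param truth A [sensor_model()] describing the simulated sensor.
#' @param noise Measurement noise std (m/s^2 for `six_position`, deg/s
#'   otherwise); per-kind default when `NULL`.
#' @param seed Integer seed.
#' @param rate Sampling rate, Hz.
#' @param n_per_pose Samples per static pose (`six_position`).
#' @param n_exec Executions per direction per axis (`ninety_deg`).
#' @param pulse_s Duration of one 90-degree execution, seconds.
#' @param static_s Static dwell around executions, seconds.
#' @param rates Turntable reference rates, deg/s.
#' @param dwell_s Seconds per turntable rate.
#' @param sweep_s Duration of the temperature sweep, seconds.
#' @param temp_range Temperature sweep range, Celsius.
#' @return An object of class `rig_recording`: `times`, `samples` (n x 3
#'   digital), `sensor` ("accel"/"gyro"), and `reference` ground truth
#'   (pose / active axis / true rate / temperature per sample).
#' @export
simulate_rig <- function(kind = c("six_position", "ninety_deg", "turntable",
                                  "temperature_sweep"),
                         truth = sensor_model(),
                         noise = NULL, seed = 1L, rate = 50,
                         n_per_pose = 200,
                         n_exec = 2, pulse_s = 2, static_s = 1.5,
                         rates = c(-(5:1), 1:5) * 100, dwell_s = 2,
                         sweep_s = 60, temp_range = c(10, 50)) {
  kind <- match.arg(kind)
  stopifnot(inherits(truth, "sensor_model"))
  set.seed(seed)
  T <- 1 / rate
  temp0 <- truth$ref_temp_c

  if (kind == "six_position") {
    if (is.null(noise)) noise <- 0.05
    g <- gravity_default()
    poses <- c("+X", "-X", "+Y", "-Y", "+Z", "-Z")
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    n <- n_per_pose * 6
    phys <- dirs[rep(seq_len(6), each = n_per_pose), ] * g
    digital <- phys %*% t(truth$accel_gain) +
      matrix(truth$accel_bias, n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, 0, noise), n, 3)
    ref <- list(pose = rep(poses, each = n_per_pose), g_mag = g)
    sensor <- "accel"
  } else if (kind == "ninety_deg") {
    if (is.null(noise)) noise <- 0.5
    # one axis block: static, +90 pulse, static, -90 pulse, ... , static
    peak <- 90 * pi / (2 * pulse_s)     # half-sine peak so the integral is 90
    n_static <- round(static_s * rate)
    n_pulse <- round(pulse_s * rate)
    pulse <- peak * sin(pi * (seq_len(n_pulse) - 0.5) / n_pulse)
    w_axis <- numeric(0)
    for (e in seq_len(2 * n_exec)) {
      sgn <- if (e %% 2 == 1) 1 else -1
      w_axis <- c(w_axis, rep(0, n_static), sgn * pulse)
    }
    w_axis <- c(w_axis, rep(0, n_static))
    nb <- length(w_axis)
    samples <- NULL; axis_ref <- NULL; w_ref <- NULL
    for (ax in 1:3) {
      w <- matrix(0, nb, 3); w[, ax] <- w_axis
      dig <- vapply(1:3, function(j) {
        gyro_forward(w[, j], truth$gyro_gain[j], truth$rate_scale[j],
                     truth$gyro_bias[j], truth$gyro_temp_coeff[j],
                     temp0, truth$ref_temp_c) + rnorm(nb, 0, noise)
      }, numeric(nb))
      samples <- rbind(samples, dig)
      axis_ref <- c(axis_ref, rep(c("x", "y", "z")[ax], nb))
      w_ref <- c(w_ref, w_axis)
    }
    n <- nrow(samples)
    digital <- samples
    ref <- list(axis = axis_ref, angle_deg = 90, true_rate = w_ref)
    sensor <- "gyro"
  } else if (kind == "turntable") {
    if (is.null(noise)) noise <- 0.5
    if (length(unique(abs(rates))) < 3) {
      stop("turntable rig needs at least 3 distinct rates", call. = FALSE)
    }
    n_dwell <- round(dwell_s * rate)
    w_axis <- rep(rates, each = n_dwell)
    nb <- length(w_axis)
    samples <- NULL; axis_ref <- NULL; w_ref <- NULL
    for (ax in 1:3) {
      w <- matrix(0, nb, 3); w[, ax] <- w_axis
      dig <- vapply(1:3, function(j) {
        gyro_forward(w[, j], truth$gyro_gain[j], truth$rate_scale[j],
                     truth$gyro_bias[j], truth$gyro_temp_coeff[j],
                     temp0, truth$ref_temp_c) + rnorm(nb, 0, noise)
      }, numeric(nb))
      samples <- rbind(samples, dig)
      axis_ref <- c(axis_ref, rep(c("x", "y", "z")[ax], nb))
      w_ref <- c(w_ref, w_axis)
    }
    n <- nrow(samples)
    digital <- samples
    ref <- list(axis = axis_ref, true_rate = w_ref)
    sensor <- "gyro"
  } else { # temperature_sweep
    if (is.null(noise)) noise <- 0.5
    n <- round(sweep_s * rate)
    temp <- seq(temp_range[1], temp_range[2], length.out = n)
    digital <- vapply(1:3, function(j) {
      gyro_forward(0, truth$gyro_gain[j], truth$rate_scale[j],
                   truth$gyro_bias[j], truth$gyro_temp_coeff[j],
                   temp, truth$ref_temp_c) + rnorm(n, 0, noise)
    }, numeric(n))
    ref <- list(temp_c = temp)
    sensor <- "gyro"
  }

  colnames(digital) <- c("x", "y", "z")
  structure(
    list(kind = kind, times = (seq_len(n) - 1) * T, rate = rate,
         sensor = sensor, samples = digital, reference = ref),
    class = "rig_recording"
  )
}

#' @export
print.rig_recording <- function(x, ...) {
  cat(sprintf("<rig_recording> kind=%s, %d samples @ %g Hz (%s)\n",
              x$kind, nrow(x$samples), x$rate, x$sensor))
  invisible(x)
}

#' Convert a physical-unit IMU recording to raw digital counts
#'
#' Applies the forward sensor error model (gains, biases, temperature drift,
#' rate-dependent gyroscope scale) to every segment of a physical recording,
#' emulating what an uncalibrated sensor would have output.  The inverse
#' operation, with a fitted model, is [apply_calibration()].
#'
#' @param rec An `imu_recording` in physical units.
#' @param truth A [sensor_model()].
#' @return The recording in digital units.
#' @export
digitize_recording <- function(rec, truth) {
  stopifnot(inherits(rec, "imu_recording"), inherits(truth, "sensor_model"))
  if (rec$units != "physical") {
    stop("recording is already digital", call. = FALSE)
  }
  n <- length(rec$times)
  for (s in names(rec$segments)) {
    a <- rec$segments[[s]]$accel
    rec$segments[[s]]$accel <- a %*% t(truth$accel_gain) +
      matrix(truth$accel_bias, n, 3, byrow = TRUE)
    w <- rec$segments[[s]]$gyro
    rec$segments[[s]]$gyro <- vapply(1:3, function(j) {
      gyro_forward(w[, j], truth$gyro_gain[j], truth$rate_scale[j],
                   truth$gyro_bias[j], truth$gyro_temp_coeff[j],
                   rec$temperature, truth$ref_temp_c)
    }, numeric(n))
    colnames(rec$segments[[s]]$gyro) <- c("x", "y", "z")
  }
  rec$units <- "digital"
  rec
}
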