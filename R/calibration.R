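# Digital-to-physical sensor calibration.
#
# All sensor models are linear: a gain matrix and bias per triad, an
# optional linear temperature drift of the gyroscope offset, and (complex
# protocol only) a linear rate dependence of the gyroscope scale.  Fits are
# ordinary least squares on simulated bench recordings.

#' Fit accelerometer gain and bias from a six-position rig recording
#'
#' Each static pose exposes one axis to +g or -g.  The mean digital reading
#' of each pose gives six equations per digital axis; a full 3x3 gain matrix
#' and 3-vector bias (12 parameters, 18 equations) are fitted by ordinary
#' least squares.
#'
#' @param rig A `six_position` [simulate_rig()] recording.
#' @param g_mag Gravity magnitude used as the physical reference, m/s^2.
#' @return List with `accel_gain` (3x3, counts per m/s^2), `accel_bias`
#'   (counts) and `residual_rms` (counts) of the fit.
#' @export
calibrate_accel_six_position <- function(rig, g_mag = gravity_default()) {
  stopifnot(inherits(rig, "rig_recording"))
  if (rig$kind != "six_position") {
    stop("rig kind must be 'six_position'", call. = FALSE)
  }
  poses <- c("+X", "-X", "+Y", "-Y", "+Z", "-Z")
  if (!all(poses %in% rig$reference$pose)) {
    missing <- setdiff(poses, unique(rig$reference$pose))
    stop("six-position protocol incomplete; missing pose(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  means <- t(vapply(poses, function(p) {
    colMeans(rig$samples[rig$reference$pose == p, , drop = FALSE])
  }, numeric(3)))
  X <- cbind(dirs * g_mag, 1)             # 6 x 4 design: [a_x a_y a_z 1]
  fit <- lm.fit(X, means)                 # one response column per digital axis
  cf <- fit$coefficients
  gain <- t(cf[1:3, , drop = FALSE])      # rows: digital axis
  bias <- as.numeric(cf[4, ])
  list(accel_gain = unname(gain), accel_bias = bias,
       residual_rms = sqrt(mean(fit$residuals^2)))
}

# internal: split one axis block of a gyro rig into static runs and
# executions by thresholding the active-axis digital signal.  The moving
# mask is dilated by `pad_s` so executions keep their low-rate tails
# (otherwise the integrated angle is clipped at the pulse edges).
split_static_runs <- function(d, rate, static_thresh, min_static_s,
                              pad_s = 0.2) {
  moving <- abs(d - stats::median(d)) >= static_thresh
  pad <- ceiling(pad_s * rate)
  if (any(moving) && pad > 0) {
    idx <- which(moving)
    lo <- pmax(idx - pad, 1)
    hi <- pmin(idx + pad, length(d))
    dilated <- logical(length(d))
    for (i in seq_along(idx)) dilated[lo[i]:hi[i]] <- TRUE
    moving <- dilated
  }
  r <- rle(!moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  min_len <- ceiling(min_static_s * rate)
  list(
    static = which(r$values & r$lengths >= min_len),
    moving = which(!r$values),
    starts = starts, ends = ends
  )
}

#' Fit gyroscope scale and bias from 90-degree executions
#'
#' Bias is the mean digital reading over the static dwells.  The scale
#' correction `c` (physical = `c * (digital - bias)`) is the one-parameter
#' least-squares fit of the integrated, bias-removed angular velocity of
#' every execution to its +/-90 degree reference:
#' `c = sum(I_e * r_e) / sum(I_e^2)` with `I_e` the integrated digital angle
#' and `r_e = 90 * sign(I_e)`.
#'
#' @param rig A `ninety_deg` [simulate_rig()] recording.
#' @param static_thresh Digital threshold (counts, approx deg/s) below which
#'   a sample counts as static.
#' @param min_static_s Minimum static-dwell duration, seconds.
#' @return List with `gyro_gain` (per-axis, counts per deg/s), `gyro_bias`
#'   (counts) and `n_executions` per axis.
#' @export
calibrate_gyro_90deg <- function(rig, static_thresh = 5, min_static_s = 0.5) {
  stopifnot(inherits(rig, "rig_recording"))
  if (rig$kind != "ninety_deg") {
    stop("rig kind must be 'ninety_deg'", call. = FALSE)
  }
  axes <- c("x", "y", "z")
  gain <- bias <- n_exec <- setNames(numeric(3), axes)
  T <- 1 / rig$rate
  for (ax in axes) {
    sel <- rig$reference$axis == ax
    d <- rig$samples[sel, ax]
    runs <- split_static_runs(d, rig$rate, static_thresh, min_static_s)
    if (length(runs$static) == 0) {
      stop("no static segment found on axis ", ax,
           "; cannot estimate bias", call. = FALSE)
    }
    static_idx <- unlist(lapply(runs$static, function(i) {
      seq(runs$starts[i], runs$ends[i])
    }))
    b <- mean(d[static_idx])
    integrals <- vapply(runs$moving, function(i) {
      idx <- seq(runs$starts[i], runs$ends[i])
      if (length(idx) < 2) return(0)
      pracma::trapz(idx * T, d[idx] - b)
    }, numeric(1))
    integrals <- integrals[abs(integrals) > 5]
    if (length(integrals) == 0) {
      stop("no usable 90-degree execution on axis ", ax,
           " (integrated angle near zero)", call. = FALSE)
    }
    r <- 90 * sign(integrals)
    corr <- sum(integrals * r) / sum(integrals^2)
    gain[ax] <- 1 / corr
    bias[ax] <- b
    n_exec[ax] <- length(integrals)
  }
  list(gyro_gain = unname(gain), gyro_bias = unname(bias),
       n_executions = unname(n_exec))
}

#' Fit gyroscope scale, bias and rate dependence from a turntable rig
#'
#' Per axis, the mean digital reading at each constant reference rate `w` is
#' regressed on `w` and `w * |w|`.  The linear coefficient is the gain, the
#' intercept the bias, and the quadratic term (normalised by the gain) the
#' linear rate dependence of the scale — the component the simplified
#' protocol cannot observe.
#'
#' @param rig A `turntable` [simulate_rig()] recording.
#' @return List with `gyro_gain`, `gyro_bias`, `rate_scale` (per axis) and
#'   `residual_rms`.
#' @export
calibrate_gyro_turntable <- function(rig) {
  stopifnot(inherits(rig, "rig_recording"))
  if (rig$kind != "turntable") {
    stop("rig kind must be 'turntable'", call. = FALSE)
  }
  axes <- c("x", "y", "z")
  gain <- bias <- rscale <- setNames(numeric(3), axes)
  resid <- 0
  for (ax in axes) {
    sel <- rig$reference$axis == ax
    d <- rig$samples[sel, ax]
    w <- rig$reference$true_rate[sel]
    ww <- sort(unique(w))
    if (length(unique(abs(ww))) < 3) {
      stop("turntable design needs >= 3 distinct rates on axis ", ax,
           call. = FALSE)
    }
    m <- vapply(ww, function(r) mean(d[w == r]), numeric(1))
    fit <- lm(m ~ ww + I(ww * abs(ww)))
    cf <- coef(fit)
    bias[ax] <- cf[1]
    gain[ax] <- cf[2]
    rscale[ax] <- cf[3] / cf[2]
    resid <- resid + sum(fit$residuals^2)
  }
  list(gyro_gain = unname(gain), gyro_bias = unname(bias),
       rate_scale = unname(rscale),
       residual_rms = sqrt(resid / (3 * length(unique(rig$reference$true_rate)))))
}

#' Fit the linear temperature model of the gyroscope offset
#'
#' Regresses the static digital gyroscope reading on temperature over the
#' sweep; the slope is the drift coefficient, reported relative to
#' `ref_temp_c`.  Temperature compensation is applied to the offset only
#' (not the scale).
#'
#' @param rig A `temperature_sweep` [simulate_rig()] recording.
#' @param ref_temp_c Reference temperature, Celsius.
#' @return List with `gyro_temp_coeff` (counts per Celsius, per axis) and
#'   `ref_temp_c`.
#' @export
fit_temperature_model <- function(rig, ref_temp_c = 25) {
  stopifnot(inherits(rig, "rig_recording"))
  if (rig$kind != "temperature_sweep") {
    stop("rig kind must be 'temperature_sweep'", call. = FALSE)
  }
  temp <- rig$reference$temp_c
  if (sd(temp) < 1e-9) {
    stop("temperature sweep is degenerate (constant temperature)",
         call. = FALSE)
  }
  tc <- vapply(1:3, function(j) {
    unname(coef(lm(rig$samples[, j] ~ temp))[2])
  }, numeric(1))
  list(gyro_temp_coeff = tc, ref_temp_c = ref_temp_c)
}

#' Run a full calibration protocol on a set of rig recordings
#'
#' The simplified protocol fits the accelerometer from the six-position rig,
#' the gyroscope from 90-degree executions, and the temperature drift from a
#' heat-chamber sweep.  The complex protocol replaces the 90-degree rig with
#' the precision turntable, adding the rate-dependent scale term; the
#' accelerometer fit is shared between the two protocols.
#'
#' @param rigs Named list of [simulate_rig()] recordings.  Requires
#'   `six_position` plus `ninety_deg` (simplified) or `turntable` (complex);
#'   `temperature_sweep` is optional.
#' @param method `"simplified"` or `"complex"`.
#' @param g_mag Gravity magnitude, m/s^2.
#' @param repetition Repetition id stored in the model.
#' @return A fitted [sensor_model()] with matching `provenance`.
#' @export
#' @examples
#' truth <- sensor_model(gyro_gain = c(1.03, 1.02, 0.99))
#' rigs <- list(
#'   six_position = simulate_rig("six_position", truth, noise = 0),
#'   ninety_deg = simulate_rig("ninety_deg", truth, noise = 0)
#' )
#' fit_calibration(rigs, "simplified")$gyro_gain
fit_calibration <- function(rigs, method = c("simplified", "complex"),
                            g_mag = gravity_default(), repetition = 1L) {
  method <- match.arg(method)
  if (is.null(rigs$six_position)) {
    stop("calibration requires a six_position rig", call. = FALSE)
  }
  acc <- calibrate_accel_six_position(rigs$six_position, g_mag)
  if (method == "simplified") {
    if (is.null(rigs$ninety_deg)) {
      stop("simplified calibration requires a ninety_deg rig", call. = FALSE)
    }
    gyr <- calibrate_gyro_90deg(rigs$ninety_deg)
    rscale <- c(0, 0, 0)
  } else {
    if (is.null(rigs$turntable)) {
      stop("complex calibration requires a turntable rig", call. = FALSE)
    }
    gyr <- calibrate_gyro_turntable(rigs$turntable)
    rscale <- gyr$rate_scale
  }
  if (!is.null(rigs$temperature_sweep)) {
    tm <- fit_temperature_model(rigs$temperature_sweep)
  } else {
    tm <- list(gyro_temp_coeff = c(0, 0, 0), ref_temp_c = 25)
  }
  sensor_model(
    accel_gain = acc$accel_gain, accel_bias = acc$accel_bias,
    gyro_gain = gyr$gyro_gain, gyro_bias = gyr$gyro_bias,
    gyro_temp_coeff = tm$gyro_temp_coeff, ref_temp_c = tm$ref_temp_c,
    rate_scale = rscale, provenance = method, repetition = repetition
  )
}

#' Transform a raw digital recording to physical units
#'
#' Inverts the linear sensor model fitted by the calibration protocols:
#' accelerometer `a = gain^-1 (d - bias)`; gyroscope
#' `w = (d - bias - temp_coeff (temp - ref)) / gain`, with the
#' rate-dependent scale `(1 + rate_scale |w|)` removed by a short fixed-point
#' iteration when present.
#'
#' @param rec An `imu_recording` in digital units.
#' @param model A fitted [sensor_model()].
#' @return The recording in physical units (m/s^2, deg/s).
#' @export
apply_calibration <- function(rec, model) {
  stopifnot(inherits(rec, "imu_recording"), inherits(model, "sensor_model"))
  if (rec$units != "digital") {
    stop("recording is already in physical units", call. = FALSE)
  }
  n <- length(rec$times)
  Ginv <- solve(model$accel_gain)
  for (s in names(rec$segments)) {
    d <- rec$segments[[s]]$accel
    a <- (d - matrix(model$accel_bias, n, 3, byrow = TRUE)) %*% t(Ginv)
    colnames(a) <- c("x", "y", "z")
    rec$segments[[s]]$accel <- a
    g <- rec$segments[[s]]$gyro
    w <- vapply(1:3, function(j) {
      raw <- (g[, j] - model$gyro_bias[j] -
                model$gyro_temp_coeff[j] * (rec$temperature - model$ref_temp_c)) /
        model$gyro_gain[j]
      s_j <- model$rate_scale[j]
      if (s_j != 0) {
        est <- raw
        for (it in 1:4) est <- raw / (1 + s_j * abs(est))
        est
      } else raw
    }, numeric(n))
    colnames(w) <- c("x", "y", "z")
    rec$segments[[s]]$gyro <- w
  }
  rec$units <- "physical"
  rec
}

#' Write a sensor model to a JSON calibration file
#'
#' @param model A [sensor_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_model <- function(model, path) {
  stopifnot(inherits(model, "sensor_model"))
  obj <- unclass(model)
  obj$accel_gain <- as.vector(obj$accel_gain)  # column-major 9-vector
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sensor model from a JSON calibration file
#'
#' @param path Path written by [write_sensor_model()].
#' @return A [sensor_model()].
#' @export
read_sensor_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sensor_model(
    accel_gain = matrix(obj$accel_gain, 3, 3),
    accel_bias = obj$accel_bias, gyro_gain = obj$gyro_gain,
    gyro_bias = obj$gyro_bias, gyro_temp_coeff = obj$gyro_temp_coeff,
    ref_temp_c = obj$ref_temp_c, rate_scale = obj$rate_scale,
    provenance = obj$provenance, repetition = obj$repetition
  )
}
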