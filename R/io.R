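# CSV/JSON/YAML interchange.  IMU gait data has no standard bioinformatics
# container, so long-format CSV with documented columns is used throughout:
#   IMU:           time_s, segment, ax, ay, az, gx, gy, gz, temp_c
#   potentiometers: time_s, hip_deg, knee_deg, ankle_deg
#   angles/truth:  time_s, segment, theta_deg [, bias_dps]
#   rigs:          time_s, x, y, z + reference columns, JSON sidecar metadata

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df[required])) {
    stop("file '", path, "' contains missing values", call. = FALSE)
  }
  invisible(df)
}

check_monotonic <- function(times, path) {
  if (is.unsorted(times, strictly = TRUE)) {
    stop("file '", path, "' has non-monotonic time_s", call. = FALSE)
  }
  invisible(times)
}

infer_rate <- function(times) {
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-6) {
    stop("non-uniform sampling; resample first", call. = FALSE)
  }
  1 / dt[1]
}

#' Write an IMU recording to long-format CSV
#'
#' @param rec An `imu_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  parts <- lapply(names(rec$segments), function(s) {
    a <- rec$segments[[s]]$accel
    g <- rec$segments[[s]]$gyro
    data.frame(time_s = rec$times, segment = s,
               ax = a[, 1], ay = a[, 2], az = a[, 3],
               gx = g[, 1], gy = g[, 2], gz = g[, 3],
               temp_c = rec$temperature)
  })
  write.csv(do.call(rbind, parts), path, row.names = FALSE)
  invisible(path)
}

#' Read an IMU recording from long-format CSV
#'
#' @param path CSV written by [write_imu_csv()].
#' @param units `"physical"` or `"digital"` — the units the file is in
#'   (CSV does not carry units).
#' @return An `imu_recording`.
#' @export
read_imu_csv <- function(path, units = c("physical", "digital")) {
  units <- match.arg(units)
  df <- read.csv(path)
  check_columns(df, c("time_s", "segment", "ax", "ay", "az",
                      "gx", "gy", "gz", "temp_c"), path)
  segs <- intersect(segment_ids(), unique(df$segment))
  if (length(segs) == 0) stop("no known segments in '", path, "'",
                              call. = FALSE)
  first <- df[df$segment == segs[1], ]
  check_monotonic(first$time_s, path)
  segments <- setNames(lapply(segs, function(s) {
    d <- df[df$segment == s, ]
    list(accel = cbind(x = d$ax, y = d$ay, z = d$az),
         gyro = cbind(x = d$gx, y = d$gy, z = d$gz))
  }), segs)
  structure(
    list(times = first$time_s, rate = infer_rate(first$time_s),
         segments = segments, temperature = first$temp_c, units = units),
    class = "imu_recording"
  )
}

#' Write a potentiometer series to CSV
#'
#' @param pots A `pot_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pots_csv <- function(pots, path) {
  stopifnot(inherits(pots, "pot_series"))
  write.csv(data.frame(time_s = pots$times,
                       hip_deg = pots$joints[, "hip"],
                       knee_deg = pots$joints[, "knee"],
                       ankle_deg = pots$joints[, "ankle"]),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a potentiometer series from CSV
#'
#' @param path CSV written by [write_pots_csv()].
#' @return A `pot_series`.
#' @export
read_pots_csv <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("time_s", "hip_deg", "knee_deg", "ankle_deg"), path)
  check_monotonic(df$time_s, path)
  structure(list(times = df$time_s, rate = infer_rate(df$time_s),
                 joints = cbind(hip = df$hip_deg, knee = df$knee_deg,
                                ankle = df$ankle_deg)),
            class = "pot_series")
}

#' Write segment angles (and optionally bias truth) to CSV
#'
#' @param series A [segment_angle_series()].
#' @param path Output path.
#' @param bias Optional matrix of true gyro biases per segment (deg/s),
#'   written as a `bias_dps` column.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(series, path, bias = NULL) {
  stopifnot(inherits(series, "segment_angle_series"))
  parts <- lapply(colnames(series$angles), function(s) {
    d <- data.frame(time_s = series$times, segment = s,
                    theta_deg = series$angles[, s])
    if (!is.null(bias)) d$bias_dps <- bias[, s]
    d
  })
  write.csv(do.call(rbind, parts), path, row.names = FALSE)
  invisible(path)
}

#' Read segment angles from CSV
#'
#' @param path CSV written by [write_angles_csv()].
#' @return A [segment_angle_series()].
#' @export
read_angles_csv <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("time_s", "segment", "theta_deg"), path)
  segs <- intersect(segment_ids(), unique(df$segment))
  first <- df[df$segment == segs[1], ]
  check_monotonic(first$time_s, path)
  angles <- vapply(segs, function(s) df$theta_deg[df$segment == s],
                   numeric(nrow(first)))
  segment_angle_series(first$time_s, angles, infer_rate(first$time_s))
}

#' Read any supported time-series CSV
#'
#' @param path Input CSV.
#' @param kind One of `"imu"`, `"pots"`, `"angles"`.
#' @param ... Passed to the specific reader.
#' @return The typed series.
#' @export
read_timeseries_csv <- function(path, kind = c("imu", "pots", "angles"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         imu = read_imu_csv(path, ...),
         pots = read_pots_csv(path),
         angles = read_angles_csv(path))
}

#' Resample a segment-angle series by cubic-spline interpolation
#'
#' Mirrors the standard practice of spline-resampling reference and
#' potentiometer data to the IMU rate.
#'
#' @param series A [segment_angle_series()].
#' @param new_rate Target rate, Hz.
#' @return A resampled [segment_angle_series()].
#' @export
resample_angles <- function(series, new_rate) {
  stopifnot(inherits(series, "segment_angle_series"))
  t_end <- series$times[length(series$times)]
  new_times <- seq(series$times[1], t_end, by = 1 / new_rate)
  angles <- vapply(colnames(series$angles), function(s) {
    spline(series$times, series$angles[, s], xout = new_times,
           method = "natural")$y
  }, numeric(length(new_times)))
  segment_angle_series(new_times, angles, new_rate)
}

#' Write a rig recording to CSV plus JSON metadata sidecar
#'
#' @param rig A [simulate_rig()] recording.
#' @param path CSV path; metadata is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_rig_csv <- function(rig, path) {
  stopifnot(inherits(rig, "rig_recording"))
  df <- data.frame(time_s = rig$times,
                   x = rig$samples[, 1], y = rig$samples[, 2],
                   z = rig$samples[, 3])
  per_sample <- Filter(function(v) length(v) == nrow(df), rig$reference)
  for (nm in names(per_sample)) df[[nm]] <- per_sample[[nm]]
  write.csv(df, path, row.names = FALSE)
  scalars <- Filter(function(v) length(v) == 1, rig$reference)
  jsonlite::write_json(
    c(list(kind = rig$kind, rate = rig$rate, sensor = rig$sensor), scalars),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a rig recording written by [write_rig_csv()]
#'
#' @param path CSV path (expects the JSON sidecar next to it).
#' @return A `rig_recording`.
#' @export
read_rig_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path)
  check_columns(df, c("time_s", "x", "y", "z"), path)
  samples <- cbind(x = df$x, y = df$y, z = df$z)
  ref_cols <- setdiff(names(df), c("time_s", "x", "y", "z"))
  reference <- c(as.list(df[ref_cols]),
                 meta[setdiff(names(meta), c("kind", "rate", "sensor"))])
  structure(list(kind = meta$kind, times = df$time_s, rate = meta$rate,
                 sensor = meta$sensor, samples = samples,
                 reference = reference),
            class = "rig_recording")
}

#' Write a filter result to CSV
#'
#' Columns: `time_s`, `segment`, `theta_hat_deg`, `updated_flag`,
#' `markov_state`.
#'
#' @param result A [run_filter()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_csv <- function(result, path) {
  stopifnot(inherits(result, "kf_result"))
  parts <- lapply(colnames(result$est$angles), function(s) {
    data.frame(time_s = result$est$times, segment = s,
               theta_hat_deg = result$est$angles[, s],
               updated_flag = as.integer(result$updates[, s]),
               markov_state = ifelse(is.na(result$update_log$markov_state),
                                     "", result$update_log$markov_state))
  })
  write.csv(do.call(rbind, parts), path, row.names = FALSE)
  invisible(path)
}

# Run configuration -----------------------------------------------------------

#' Read and validate a run configuration from YAML
#'
#' Recognized top-level keys: `gait` (arguments of [gait_config()]),
#' `truth` (arguments of [sensor_model()]), `protocol` (arguments of
#' [eval_protocol()]), `params` (filter parameters), `zeta`, `seeds`,
#' `filters`.  Unknown keys are an error so that typos surface early.
#'
#' @param path YAML file.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("gait", "truth", "protocol", "params", "zeta", "seeds",
               "filters")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$gait)) do.call(gait_config, cfg$gait)   # validates
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param cfg A named list (or `run_config`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
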