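# Reading, resampling, tilt correction and filtering of raw lumbar-IMU trials.

#' Construct a raw IMU recording object
#'
#' @param t time stamps in seconds (strictly increasing).
#' @param ax,ay,az triaxial acceleration in g, sensor frame.
#' @param gx,gy,gz triaxial angular velocity in deg/s, sensor frame.
#' @param fs_nominal nominal sampling rate in Hz.
#' @return an object of class `"imu_recording"`: a data frame with columns
#'   `t, ax, ay, az, gx, gy, gz` and attribute `fs_nominal`.
#' @export
imu_recording <- function(t, ax, ay, az, gx, gy, gz, fs_nominal = 31.25) {
  n <- length(t)
  lens <- c(length(ax), length(ay), length(az),
            length(gx), length(gy), length(gz))
  if (any(lens != n)) {
    stop("all channels must have the same length as t", call. = FALSE)
  }
  if (n >= 2L && any(diff(t) <= 0)) {
    stop("time stamps must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(fs_nominal) || fs_nominal <= 0) {
    stop("fs_nominal must be a positive number", call. = FALSE)
  }
  rec <- data.frame(t = t, ax = ax, ay = ay, az = az,
                    gx = gx, gy = gy, gz = gz)
  attr(rec, "fs_nominal") <- fs_nominal
  class(rec) <- c("imu_recording", "data.frame")
  rec
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples, %.2f s, fs_nominal = %g Hz\n",
              nrow(x), diff(range(x$t)), attr(x, "fs_nominal")))
  invisible(x)
}

#' Read a raw recording CSV
#'
#' Expects a header with columns `t, ax, ay, az, gx, gy, gz`
#' (time in seconds, acceleration in g, angular velocity in deg/s).
#' Time stamps are re-zeroed to seconds since the first sample.
#'
#' @param path path to the CSV file.
#' @param fs_nominal nominal sampling rate in Hz.
#' @return an [imu_recording()].
#' @export
read_recording <- function(path, fs_nominal = 31.25) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("recording is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) >= 2L && any(diff(d$t) <= 0)) {
    stop("recording time stamps are not strictly increasing", call. = FALSE)
  }
  imu_recording(d$t - d$t[1L], d$ax, d$ay, d$az, d$gx, d$gy, d$gz,
                fs_nominal = fs_nominal)
}

#' Write a recording to CSV (round-trips with [read_recording()])
#'
#' Values are written with 17 significant digits so the file round-trips
#' bit-identically through [read_recording()].
#'
#' @param rec an [imu_recording()].
#' @param path output path.
#' @export
write_recording <- function(rec, path) {
  cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  d <- as.data.frame(rec)[, cols]
  lines <- c(paste(cols, collapse = ","),
             do.call(paste, c(lapply(d, function(x) sprintf("%.17g", x)),
                              sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trial annotation CSV (`trial_id,test,t_start,t_end`)
#'
#' @param path path to the CSV file.
#' @return a data frame with those four columns.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "test", "t_start", "t_end")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("annotation file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(d$t_start >= d$t_end)) {
    stop("annotations must satisfy t_start < t_end", call. = FALSE)
  }
  if (anyDuplicated(d$trial_id)) {
    stop("trial_id values must be unique", call. = FALSE)
  }
  d
}

#' Read subject metadata (CSV or YAML)
#'
#' Fields: `subject_id, age, sex, height_cm, weight_kg, shoe_size,
#' sensor_to_ground_m`.  `sensor_to_ground_m` is the pendulum length L of the
#' step-length model (distance from the lower-back sensor to the ground).
#'
#' @param path path to a `.csv` or `.yaml`/`.yml` file.
#' @return a named list.
#' @export
read_subject_meta <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML metadata",
           call. = FALSE)
    }
    m <- yaml::read_yaml(path)
  } else {
    m <- as.list(utils::read.csv(path, stringsAsFactors = FALSE)[1L, ])
  }
  need <- c("subject_id", "height_cm", "weight_kg", "shoe_size",
            "sensor_to_ground_m")
  missing_fields <- setdiff(need, names(m))
  if (length(missing_fields)) {
    stop("subject metadata is missing field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  if (m$sensor_to_ground_m >= m$height_cm / 100) {
    stop("sensor_to_ground_m must be smaller than the height in metres",
         call. = FALSE)
  }
  m
}

#' Resample a recording onto a uniform time grid
#'
#' Linear interpolation of every channel onto `t0 + k/fs`, covering the
#' original time span; output length is `floor((tN - t0) * fs) + 1`.
#' Device time stamps jitter around the nominal rate, so all downstream
#' algorithms assume this uniform grid.
#'
#' @param rec an [imu_recording()].
#' @param fs target sampling rate in Hz (defaults to the nominal rate).
#' @return an [imu_recording()] on the uniform grid.
#' @export
resample_uniform <- function(rec, fs = attr(rec, "fs_nominal")) {
  if (nrow(rec) < 2L) {
    stop("resampling needs at least 2 samples", call. = FALSE)
  }
  t0 <- rec$t[1L]
  tN <- rec$t[nrow(rec)]
  tq <- t0 + seq(0L, floor((tN - t0) * fs)) / fs
  ch <- lapply(c("ax", "ay", "az", "gx", "gy", "gz"), function(nm) {
    stats::approx(rec$t, rec[[nm]], xout = tq, rule = 2)$y
  })
  out <- imu_recording(tq, ch[[1L]], ch[[2L]], ch[[3L]],
                       ch[[4L]], ch[[5L]], ch[[6L]], fs_nominal = fs)
  attr(out, "fs") <- fs
  out
}

#' Estimate sensor tilt angles from mean acceleration
#'
#' The tilt of the device about its x and z axes relative to the horizontal
#' plane is estimated from the mean measured acceleration in g, using
#' `sin(theta) ~ mean(a)`: with the sensor near-vertical, gravity projects
#' onto the tilted x and z axes in proportion to the sine of each tilt angle.
#' By default the mean is taken over the whole trial; pass `window` to
#' restrict it to a known static segment.
#'
#' @param rec an [imu_recording()].
#' @param window optional integer vector of sample indices to average over.
#' @return named numeric `c(theta_x, theta_z)` in radians.
#' @export
estimate_tilt <- function(rec, window = NULL) {
  idx <- window %||% seq_len(nrow(rec))
  fs <- attr(rec, "fs") %||% attr(rec, "fs_nominal")
  if (length(idx) < fs) {
    warning("tilt window shorter than 1 s; estimate may be unstable")
  }
  mx <- mean(rec$ax[idx])
  mz <- mean(rec$az[idx])
  if (abs(mx) > 1 || abs(mz) > 1) {
    warning("mean acceleration exceeds 1 g; check that input is in g units")
    mx <- max(-1, min(1, mx))
    mz <- max(-1, min(1, mz))
  }
  c(theta_x = asin(mx), theta_z = asin(mz))
}

#' Rotate a recording into anatomical axes and remove gravity
#'
#' Applies the two-stage tilt correction: a provisional vertical acceleration
#' `a^V = az*sin(theta_z) + ay*cos(theta_z)` and anteroposterior
#' `aAP = -az*cos(theta_z) + ay*sin(theta_z)`, then
#' `aML = -ax*cos(theta_x) + a^V*sin(theta_x)` and
#' `aV = ax*sin(theta_x) + a^V*cos(theta_x) - 1`, removing the static 1 g.
#' The three dynamic accelerations are then converted to m/s^2.  Gyro channels
#' are mapped to anatomical pitch (about the mediolateral axis) and yaw (about
#' the vertical axis) via `config$gyro_map`.
#'
#' @param rec an [imu_recording()] (uniformly sampled; see
#'   [resample_uniform()]).
#' @param theta_x,theta_z tilt angles in radians (see [estimate_tilt()]).
#' @param config an [lg_config()].
#' @return an object of class `"aligned_signal"`: data frame with columns
#'   `t, aAP, aML, aV` (m/s^2, gravity removed) and `pitch, yaw` (deg/s), with
#'   attributes `fs`, `theta_x`, `theta_z`.
#' @export
to_anatomical <- function(rec, theta_x, theta_z, config = lg_config()) {
  g <- config$gravity
  cx <- cos(theta_x); sx <- sin(theta_x)
  cz <- cos(theta_z); sz <- sin(theta_z)
  a_hat_v <- rec$az * sz + rec$ay * cz
  aAP <- -rec$az * cz + rec$ay * sz
  aML <- -rec$ax * cx + a_hat_v * sx
  aV  <- rec$ax * sx + a_hat_v * cx - 1
  gm <- config$gyro_map
  pitch <- gm$pitch_sign * rec[[gm$pitch]]
  yaw   <- gm$yaw_sign * rec[[gm$yaw]]
  out <- data.frame(t = rec$t,
                    aAP = aAP * g, aML = aML * g, aV = aV * g,
                    pitch = pitch, yaw = yaw)
  attr(out, "fs") <- attr(rec, "fs") %||% attr(rec, "fs_nominal")
  attr(out, "theta_x") <- theta_x
  attr(out, "theta_z") <- theta_z
  class(out) <- c("aligned_signal", "data.frame")
  out
}

#' @export
print.aligned_signal <- function(x, ...) {
  cat(sprintf("<aligned_signal> %d samples at %g Hz (%.2f s)\n",
              nrow(x), attr(x, "fs"), diff(range(x$t))))
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward filtering (`signal::filtfilt`) so that event times are not
#' lagged by the filter.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param order filter order (of the underlying one-pass filter).
#' @return filtered series, same length.
#' @export
butterworth_lowpass <- function(x, fs, cutoff, order = 4) {
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, fs / 2), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtfilt_padded(bf, x)
}

# forward-backward filtering with odd-reflection end padding (suppresses the
# start/end transients of plain filtfilt)
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  k <- min(n - 1L, 3L * (max(length(bf$a), length(bf$b)) - 1L) * 4L)
  pre <- 2 * x[1L] - x[(k + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - k)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(k + 1L):(k + n)]
}

#' Preprocess one annotated trial
#'
#' Resamples to a uniform grid, estimates tilt (over the full trial by
#' default), rotates to anatomical axes with gravity removed, and applies the
#' walking-test filters: 10 Hz low-pass on the accelerations (`aAP_f`,
#' `aML_f`, `aV_f`, only when `walking = TRUE`) and a 2 Hz low-pass on yaw
#' (`yaw_f`) used for left/right assignment.
#'
#' @param rec an [imu_recording()].
#' @param window optional `c(t_start, t_end)` in seconds: the annotated trial
#'   window the output is restricted to (tilt is still estimated from the
#'   full recording).
#' @param walking logical: apply the 10 Hz walking low-pass.
#' @param tilt_window optional static-window override for [estimate_tilt()].
#' @param config an [lg_config()].
#' @return an `"aligned_signal"` with filtered channels appended.
#' @export
preprocess_trial <- function(rec, window = NULL, walking = FALSE,
                             tilt_window = NULL, config = lg_config()) {
  fs <- config$fs
  ur <- resample_uniform(rec, fs)
  th <- estimate_tilt(ur, window = tilt_window)
  sig <- to_anatomical(ur, th[["theta_x"]], th[["theta_z"]], config)
  sig$yaw_f <- butterworth_lowpass(sig$yaw, fs, config$yaw_lowpass_hz,
                                   config$yaw_lowpass_order)
  if (walking) {
    sig$aAP_f <- butterworth_lowpass(sig$aAP, fs, config$lowpass_walk_hz,
                                     config$lowpass_walk_order)
    sig$aML_f <- butterworth_lowpass(sig$aML, fs, config$lowpass_walk_hz,
                                     config$lowpass_walk_order)
    sig$aV_f  <- butterworth_lowpass(sig$aV, fs, config$lowpass_walk_hz,
                                     config$lowpass_walk_order)
  }
  if (!is.null(window)) {
    keep <- sig$t >= window[1L] - 1e-9 & sig$t <= window[2L] + 1e-9
    at <- attributes(sig)
    sig <- sig[keep, , drop = FALSE]
    rownames(sig) <- NULL
    attr(sig, "fs") <- at$fs
    attr(sig, "theta_x") <- at$theta_x
    attr(sig, "theta_z") <- at$theta_z
    class(sig) <- c("aligned_signal", "data.frame")
  }
  sig
}
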