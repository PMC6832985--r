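# Shared helpers for event-matching and signal fixtures (built in code).

# recall/precision of detected event times against ground truth
match_stats <- function(t_true, t_det, tol) {
  if (!length(t_det)) return(c(recall = 0, precision = NA_real_))
  rec <- mean(vapply(t_true, function(ti) min(abs(t_det - ti)) <= tol,
                     logical(1)))
  prec <- mean(vapply(t_det, function(td) min(abs(t_true - td)) <= tol,
                      logical(1)))
  c(recall = rec, precision = prec)
}

# uniform-grid time vector
tgrid <- function(duration, fs) seq(0, duration, by = 1 / fs)

# static recording with gravity along a tilted sensor frame, built from the
# exact inverse of the anatomical transform
static_recording <- function(theta_x = 0, theta_z = 0, duration = 4,
                             fs = 31.25) {
  t <- tgrid(duration, fs)
  n <- length(t)
  sf <- lumbargait:::.to_sensor_frame(rep(0, n), rep(0, n), rep(0, n),
                                      theta_x, theta_z, 9.81)
  imu_recording(t, sf$ax, sf$ay, sf$az, rep(0, n), rep(0, n), rep(0, n),
                fs_nominal = fs)
}

rms <- function(x) sqrt(mean(x^2))
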