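# Seed-deterministic lumbar-IMU signal generators with exact ground truth.
#
# The walking generator scripts the vertical centre-of-mass displacement as a
# small Fourier series (one oscillation per step plus asymmetry sidebands)
# and emits the acceleration that is its second derivative under DISCRETE
# trapezoid integration: each frequency component is scaled by
# (tan(w/(2 fs)) / (w/(2 fs)))^2 so that double cumulative-trapezoid
# integration at the output rate recovers the programmed displacement, which
# is what licenses the step-length tests.  Ground-truth contacts sit at the
# displacement minima.

# trapezoid-rule gain compensation for angular frequency w at rate fs
.trapz_comp <- function(w, fs) {
  x <- w / (2 * fs)
  (tan(x) / x)^2
}

# smooth 0->1->0 envelope phase-locked to the vertical oscillation: the
# ramp-up spans the displacement's rising zero crossing (0.05/f) to its first
# maximum (0.3/f) and the ramp-down the last maximum ((n+0.3)/f) to the next
# zero crossing, so the enveloped cosine is monotone within each ramp and no
# spurious displacement minima (false contacts) are created at the walk
# boundaries.
.walk_envelope <- function(tw, f_step, n_steps) {
  r <- 0.25 / f_step
  t_on <- 0.05 / f_step
  t_off <- (n_steps + 0.3) / f_step
  e <- numeric(length(tw))
  e[tw >= t_on + r & tw <= t_off] <- 1
  up <- tw > t_on & tw < t_on + r
  e[up] <- 0.5 * (1 - cos(pi * (tw[up] - t_on) / r))
  dn <- tw > t_off & tw < t_off + r
  e[dn] <- 0.5 * (1 + cos(pi * (tw[dn] - t_off) / r))
  e
}

# analytic walking vertical displacement and compensated acceleration.
# u = pi*f*tw - 0.3*pi ; d = -c (1 - 2a cos u) cos 2u  (c = h_amp/2):
# the per-step troughs (2u = 0 mod 2pi) are scaled (1 + a) / (1 - a) on
# alternating steps while the shared maxima (the contacts, 2u = pi) stay at
# +c, so each step's peak-to-trough excursion is h_amp * (1 +/- asym).
# Expansion: d = -c cos 2u + a c cos 3u + a c cos u.
.walk_vertical <- function(tw, f_step, h_amp, asym, fs, envelope) {
  c0 <- h_amp / 2
  a <- asym
  u <- pi * f_step * tw - 0.3 * pi
  w1 <- 2 * pi * f_step      # cos 2u term
  w3 <- 3 * pi * f_step      # cos 3u sideband
  wu <- pi * f_step          # cos u sideband
  d <- -(c0 * cos(2 * u)) + a * c0 * cos(3 * u) + a * c0 * cos(u)
  aV <- c0 * w1^2 * .trapz_comp(w1, fs) * cos(2 * u) -
    a * c0 * w3^2 * .trapz_comp(w3, fs) * cos(3 * u) -
    a * c0 * wu^2 * .trapz_comp(wu, fs) * cos(u)
  list(d = d * envelope, aV = aV * envelope, u = u)
}

# project true-frame dynamics (m/s^2) plus gravity into the tilted sensor
# frame (g units); the exact inverse of the anatomical transform
.to_sensor_frame <- function(aAP, aML, aV, theta_x, theta_z, gravity) {
  cx <- cos(theta_x); sx <- sin(theta_x)
  cz <- cos(theta_z); sz <- sin(theta_z)
  aAP_g <- aAP / gravity
  aML_g <- aML / gravity
  aVt_g <- aV / gravity + 1      # total vertical incl. gravity
  ax <- -aML_g * cx + aVt_g * sx
  a_hat <- aML_g * sx + aVt_g * cx
  az <- sz * a_hat - cz * aAP_g
  ay <- cz * a_hat + sz * aAP_g
  list(ax = ax, ay = ay, az = az)
}

# gaus1-shaped (odd) heel-strike transient, peak amplitude `amp`
.transient_train <- function(t, centres, amp, width) {
  out <- numeric(length(t))
  for (tc in centres) {
    s <- (t - tc) / width
    out <- out - amp * exp(0.5) * s * exp(-s^2 / 2)
  }
  out
}

#' Generate a synthetic straight-walking trial with known contacts
#'
#' The vertical centre-of-mass displacement oscillates once per step with
#' peak-to-trough excursion `h_amp` (scaled `(1 +/- asym)` towards alternate
#' sides); initial contacts are scripted at the displacement minima, end
#' contacts one double-support offset (0.2 step) later, and the yaw channel
#' is a half-step-frequency sinusoid phase-locked so that side "A" contacts
#' see non-negative yaw.  Short gaus1-shaped heel-strike transients are added
#' at each contact, white Gaussian noise on every channel, and gravity plus a
#' programmed static tilt take the signals into the sensor frame.  Standing
#' pads surround the annotated walking window.
#'
#' @param f_step step frequency, Hz (0.5 to 4).
#' @param n_steps number of steps (initial contacts).
#' @param h_amp vertical excursion per step, m (0 < h_amp < L).
#' @param L pendulum length, m (sensor-to-ground distance).
#' @param asym side asymmetry fraction of `h_amp`.
#' @param noise_sd accelerometer noise, m/s^2.
#' @param seed RNG seed (deterministic output).
#' @param fs sampling rate, Hz.
#' @param pad standing pad before/after the walking window, s.
#' @param theta_x,theta_z programmed static tilt, radians.
#' @param yaw_amp walking yaw amplitude, deg/s.
#' @param transient_amp heel-strike transient amplitude, m/s^2.
#' @return list with `recording` (an [imu_recording()]), `annotation`
#'   (one-row data frame), and `truth` (list: `t_ic`, `t_ec`, `side`, `h`,
#'   `step_length` = pendulum lengths from `h` and `L`, `f_step`, `window`,
#'   `disp` = programmed displacement over the window).
#' @export
gen_walk <- function(f_step = 1.8, n_steps = 20L, h_amp = 0.05, L = 1.0,
                     asym = 0, noise_sd = 0.1, seed = 1L, fs = 31.25,
                     pad = 1.0, theta_x = deg2rad(2), theta_z = deg2rad(1),
                     yaw_amp = 10, transient_amp = 0.3) {
  if (f_step < 0.5 || f_step > 4) {
    stop("f_step must lie in [0.5, 4] Hz", call. = FALSE)
  }
  if (h_amp <= 0 || h_amp >= L) {
    stop("h_amp must satisfy 0 < h_amp < L", call. = FALSE)
  }
  set.seed(seed)
  gravity <- 9.81
  T_walk <- (n_steps + 0.5) / f_step
  t_tot <- pad + T_walk + pad
  t <- seq(0L, floor(t_tot * fs)) / fs
  tw <- t - pad
  env <- .walk_envelope(tw, f_step, n_steps)
  wv <- .walk_vertical(tw, f_step, h_amp, asym, fs, env)
  u <- wv$u

  t_ic <- pad + (seq_len(n_steps) - 1 + 0.8) / f_step
  t_ec <- t_ic + 0.2 / f_step
  side <- rep_len(c("A", "B"), n_steps)

  aV <- wv$aV + .transient_train(t, t_ic, transient_amp, 0.04) +
    stats::rnorm(length(t), 0, noise_sd)
  aAP <- env * 0.8 * cos(2 * u + 0.5) + stats::rnorm(length(t), 0, noise_sd)
  aML <- env * 0.5 * sin(u + 0.3) + stats::rnorm(length(t), 0, noise_sd)
  yaw <- env * yaw_amp * sin(u) + stats::rnorm(length(t), 0, 0.8)
  pitch <- env * 2 * sin(2 * u) + stats::rnorm(length(t), 0, 0.8)

  sf <- .to_sensor_frame(aAP, aML, aV, theta_x, theta_z, gravity)
  rec <- imu_recording(t, sf$ax, sf$ay, sf$az,
                       gx = pitch, gy = yaw,
                       gz = stats::rnorm(length(t), 0, 0.5),
                       fs_nominal = fs)

  # per-step excursion of the clean displacement on a fine grid
  tf <- seq(pad, pad + T_walk, by = 1 / (8 * fs))
  df <- .walk_vertical(tf - pad, f_step, h_amp, asym, fs,
                       .walk_envelope(tf - pad, f_step, n_steps))$d
  h <- vapply(seq_len(n_steps - 1L), function(i) {
    sel <- tf >= t_ic[i] & tf <= t_ic[i + 1L]
    diff(range(df[sel]))
  }, numeric(1))

  win <- t >= pad & t <= pad + T_walk
  truth <- list(t_ic = t_ic, t_ec = t_ec, side = side, h = h,
                step_length = pendulum_step_length(h, L),
                f_step = f_step, window = c(pad, pad + T_walk),
                disp = data.frame(t = t[win], d = wv$d[win]))
  list(recording = rec,
       annotation = data.frame(trial_id = "walk", test = "10MWT_SSV",
                               t_start = pad, t_end = pad + T_walk),
       truth = truth)
}

#' Generate a synthetic quiet-standing (sway) trial
#'
#' AP/ML accelerations are band-limited Gaussian noise whose sample
#' covariance is driven exactly to `cov` by empirical whitening and
#' recolouring; gravity with a programmed tilt is added in the sensor frame.
#'
#' @param cov 2x2 symmetric positive semi-definite covariance (m^2/s^4),
#'   AP first.
#' @param band pass band, Hz.
#' @param duration trial length, s.
#' @param seed RNG seed.
#' @param fs sampling rate, Hz.
#' @param theta_x,theta_z programmed static tilt, radians.
#' @return list with `recording`, `annotation` and `truth` (`cov`, `band`).
#' @export
gen_sway <- function(cov = diag(c(0.03, 0.02)^2), band = c(0.1, 2),
                     duration = 30, seed = 1L, fs = 31.25,
                     theta_x = deg2rad(2), theta_z = deg2rad(1)) {
  if (!isTRUE(all.equal(cov, t(cov))) || any(eigen(cov)$values < -1e-12)) {
    stop("cov must be symmetric positive semi-definite", call. = FALSE)
  }
  set.seed(seed)
  n <- floor(duration * fs) + 1L
  X <- matrix(stats::rnorm(2L * n), ncol = 2L)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  X <- apply(X, 2L, function(col) filtfilt_padded(bf, col))
  X <- sweep(X, 2L, colMeans(X))
  if (all(cov == 0)) {
    X[] <- 0
  } else {
    S <- stats::cov(X)
    X <- X %*% solve(chol(S)) %*% chol(cov)
  }
  t <- seq_len(n - 1L + 1L)
  t <- (seq_len(n) - 1L) / fs
  aV <- stats::rnorm(n, 0, 0.01)
  sf <- .to_sensor_frame(X[, 1L], X[, 2L], aV, theta_x, theta_z, 9.81)
  rec <- imu_recording(t, sf$ax, sf$ay, sf$az,
                       gx = stats::rnorm(n, 0, 0.5),
                       gy = stats::rnorm(n, 0, 0.5),
                       gz = stats::rnorm(n, 0, 0.5), fs_nominal = fs)
  list(recording = rec,
       annotation = data.frame(trial_id = "sway", test = "BBS_SU",
                               t_start = 0, t_end = t[n]),
       truth = list(cov = cov, band = band))
}

#' Generate a scripted synthetic Timed Up and Go trial
#'
#' Pitch shows Gaussian-shaped bursts at sit-to-stand and stand-to-sit, yaw
#' at the two 180-degree turns, and the two 3 m walking segments reuse the
#' walking generator's vertical-displacement script.  Ground-truth landmarks
#' are the analytic threshold crossings of the clean script under the same
#' rules the detector applies (10% of the extremum for pitch phases, 15% of
#' the global yaw maximum for turns).
#'
#' @param steps_per_walk steps in each walking segment.
#' @param f_step walking step frequency, Hz.
#' @param sts_peak,sit_peak pitch burst peaks, deg/s (sit peak typically
#'   opposite in sign).
#' @param turn_peaks length-2 yaw burst peaks, deg/s.
#' @param sigma_sts,sigma_turn Gaussian burst widths, s.
#' @param h_amp walking vertical excursion, m.
#' @param noise_sd accelerometer noise, m/s^2.
#' @param seed RNG seed.
#' @param fs sampling rate, Hz.
#' @return list with `recording`, `annotation` and `truth` (`phases` data
#'   frame with scripted `t_i, t_ii, t_iii` per phase, `walk_t_ic`,
#'   `walk_steps`, `f_step`).
#' @export
gen_tug <- function(steps_per_walk = 6L, f_step = 1.8, sts_peak = 50,
                    sit_peak = -45, turn_peaks = c(60, 70),
                    sigma_sts = 0.5, sigma_turn = 0.45, h_amp = 0.04,
                    noise_sd = 0.1, seed = 1L, fs = 31.25) {
  set.seed(seed)
  gravity <- 9.81
  gap <- 0.4
  amp_frac <- 0.10
  turn_frac <- 0.15

  half_sts <- sigma_sts * sqrt(2 * log(1 / amp_frac))
  thr <- turn_frac * max(abs(turn_peaks))
  half_turn <- sigma_turn * sqrt(2 * log(abs(turn_peaks) / thr))

  T_w <- (steps_per_walk + 0.5) / f_step
  sts_i <- 1.0
  sts_c <- sts_i + half_sts
  sts_iii <- sts_c + half_sts
  w1_start <- sts_iii + gap
  w1_end <- w1_start + T_w
  t1_i <- w1_end + gap
  t1_c <- t1_i + half_turn[1L]
  t1_iii <- t1_c + half_turn[1L]
  w2_start <- t1_iii + gap
  w2_end <- w2_start + T_w
  t2_i <- w2_end + gap
  t2_c <- t2_i + half_turn[2L]
  t2_iii <- t2_c + half_turn[2L]
  sit_i <- t2_iii + 0.2
  sit_c <- sit_i + half_sts
  sit_iii <- sit_c + half_sts
  t_tot <- sit_iii + 1.2

  t <- seq(0L, floor(t_tot * fs)) / fs
  n <- length(t)
  gauss <- function(tc, s) exp(-(t - tc)^2 / (2 * s^2))

  pitch <- sts_peak * gauss(sts_c, sigma_sts) +
    sit_peak * gauss(sit_c, sigma_sts)
  yaw <- turn_peaks[1L] * gauss(t1_c, sigma_turn) +
    turn_peaks[2L] * gauss(t2_c, sigma_turn)

  aV <- stats::rnorm(n, 0, noise_sd)
  aAP <- 0.5 * sts_peak / 50 * gauss(sts_c, sigma_sts) +
    0.5 * abs(sit_peak) / 50 * gauss(sit_c, sigma_sts) +
    stats::rnorm(n, 0, noise_sd)
  aML <- stats::rnorm(n, 0, noise_sd)
  walk_t_ic <- c()
  for (ws in c(w1_start, w2_start)) {
    tw <- t - ws
    env <- .walk_envelope(tw, f_step, steps_per_walk)
    wv <- .walk_vertical(tw, f_step, h_amp, 0, fs, env)
    aV <- aV + wv$aV
    u <- wv$u
    aAP <- aAP + env * 0.6 * cos(2 * u + 0.5)
    aML <- aML + env * 0.4 * sin(u + 0.3)
    yaw <- yaw + env * 5 * sin(u)
    pitch <- pitch + env * 1.5 * sin(2 * u)
    ics <- ws + (seq_len(steps_per_walk) - 1 + 0.8) / f_step
    aV <- aV + .transient_train(t, ics, 0.25, 0.04)
    walk_t_ic <- c(walk_t_ic, ics)
  }
  pitch <- pitch + stats::rnorm(n, 0, 0.8)
  yaw <- yaw + stats::rnorm(n, 0, 0.8)

  sf <- .to_sensor_frame(aAP, aML, aV, deg2rad(2), deg2rad(1), gravity)
  rec <- imu_recording(t, sf$ax, sf$ay, sf$az, gx = pitch, gy = yaw,
                       gz = stats::rnorm(n, 0, 0.5), fs_nominal = fs)

  phases <- data.frame(
    phase = c("STS", "WALK1", "TURN1", "WALK2", "TURN2", "StS"),
    t_i = c(sts_i, sts_iii, t1_i, t1_iii, t2_i, sit_i),
    t_ii = c(sts_c, (sts_iii + t1_i) / 2, t1_c, (t1_iii + t2_i) / 2, t2_c,
             sit_c),
    t_iii = c(sts_iii, t1_i, t1_iii, t2_i, t2_iii, sit_iii),
    stringsAsFactors = FALSE)

  list(recording = rec,
       annotation = data.frame(trial_id = "tug", test = "TUG",
                               t_start = 0, t_end = t[n]),
       truth = list(phases = phases, walk_t_ic = walk_t_ic,
                    walk_steps = 2L * steps_per_walk, f_step = f_step))
}

#' Default synthetic subject profile
#' @return named list of subject and gait parameters used by
#'   [gen_session()].
#' @export
default_profile <- function() {
  list(subject_id = "SYN01", age = 30, sex = "F", height_cm = 170,
       weight_kg = 70,
       # shoe size in the metre-scaled convention matching the shipped K
       shoe_size = 0.09,
       sensor_to_ground_m = 1.0,
       v_ssv = 1.3, v_fv = 1.6, f_ssv = 1.8, f_fv = 2.0)
}

#' Generate a complete synthetic test session
#'
#' Emulates the full clinical battery: three 10 m walk trials at
#' self-selected and three at fast velocity, the five static balance
#' conditions, two Timed Up and Go trials and one naturalistic walking bout.
#' Walking excursions are derived from the profile's programmed velocities
#' so that the corrected step length matches the scripted speed under the
#' configured K values.
#'
#' @param profile subject profile (see [default_profile()]).
#' @param seed RNG seed; per-trial seeds are derived from it.
#' @param config an [lg_config()].
#' @return list with `recordings` (named list of [imu_recording()]),
#'   `annotations` (data frame), `meta` (named list) and `truth` (per-trial
#'   ground truth).
#' @export
gen_session <- function(profile = default_profile(), seed = 1L,
                        config = lg_config()) {
  fs <- config$fs
  L <- profile$sensor_to_ground_m
  S <- profile$shoe_size
  recs <- list(); anns <- list(); truth <- list()
  sub_seed <- function(k) (seed * 131L + k) %% .Machine$integer.max

  add <- function(id, test, gen) {
    gen$annotation$trial_id <- id
    gen$annotation$test <- test
    recs[[id]] <<- gen$recording
    anns[[id]] <<- gen$annotation
    truth[[id]] <<- gen$truth
  }

  h_for <- function(v, f, K) {
    ls_target <- v / f
    pend <- ls_target - K * S
    if (pend <= 0 || pend / 2 >= L) {
      stop("profile velocity incompatible with pendulum geometry",
           call. = FALSE)
    }
    L - sqrt(L^2 - (pend / 2)^2)
  }

  k <- 0L
  for (cond in c("SSV", "FV")) {
    v <- if (cond == "SSV") profile$v_ssv else profile$v_fv
    f <- if (cond == "SSV") profile$f_ssv else profile$f_fv
    h <- h_for(v, f, config$K[[cond]])
    n_steps <- round(10 / (v / f))
    for (i in 1:3) {
      k <- k + 1L
      add(sprintf("%s%d", tolower(cond), i), paste0("10MWT_", cond),
          gen_walk(f_step = f, n_steps = n_steps, h_amp = h, L = L,
                   seed = sub_seed(k), fs = fs))
    }
  }
  bbs_scale <- c(SU = 1, SEC = 1.3, SFT = 1.2, ST = 1.5, SOL = 2)
  for (cond in names(bbs_scale)) {
    k <- k + 1L
    add(paste0("bbs_", tolower(cond)), paste0("BBS_", cond),
        gen_sway(cov = bbs_scale[[cond]]^2 * diag(c(0.03, 0.02)^2),
                 duration = 30, seed = sub_seed(k), fs = fs))
  }
  for (i in 1:2) {
    k <- k + 1L
    add(sprintf("tug%d", i), "TUG",
        gen_tug(seed = sub_seed(k), fs = fs, f_step = profile$f_ssv))
  }
  k <- k + 1L
  h_nat <- h_for(profile$v_ssv, profile$f_ssv, config$K[["SSV"]])
  add("natwalk", "NATWALK",
      gen_walk(f_step = profile$f_ssv, n_steps = 40L, h_amp = h_nat, L = L,
               seed = sub_seed(k), fs = fs))

  meta <- list(subject_id = profile$subject_id, age = profile$age,
               sex = profile$sex, height_cm = profile$height_cm,
               weight_kg = profile$weight_kg, shoe_size = S,
               sensor_to_ground_m = L)
  list(recordings = recs, annotations = do.call(rbind, anns),
       meta = meta, truth = truth)
}

#' Write a generated session to disk in the pipeline's input formats
#'
#' One CSV per recording (full double precision, so files round-trip
#' bit-identically through [read_recording()]), plus `annotations.csv` and
#' `meta.csv`.
#'
#' @param session result of [gen_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(session$recordings)) {
    write_recording(session$recordings[[id]],
                    file.path(dir, paste0(id, ".csv")))
  }
  utils::write.csv(session$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(session$meta), file.path(dir, "meta.csv"),
                   row.names = FALSE)
  invisible(dir)
}
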