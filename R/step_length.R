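# Inverted-pendulum step length with shoe-size correction.

#' Per-step vertical excursion of the centre of mass
#'
#' `h(i)` is the peak-to-trough displacement within the step interval
#' `[tIC(i), tIC(i+1))`.  The displacement is obtained by double drift-free
#' integration of the vertical acceleration (see
#' [emd_drift_free_integral()]).
#'
#' @param disp drift-free vertical displacement series (m).
#' @param events a `gait_events` object with at least 2 initial contacts.
#' @param fs sampling rate of `disp`, Hz.
#' @param t0 time of the first `disp` sample.
#' @return numeric vector of per-step height changes `h` (length
#'   `n_ic - 1`); steps whose window holds fewer than 3 samples are `NA`.
#' @export
step_height <- function(disp, events, fs, t0 = 0) {
  t_ic <- events$t_ic
  if (length(t_ic) < 2L) return(numeric(0))
  tt <- t0 + (seq_along(disp) - 1L) / fs
  vapply(seq_len(length(t_ic) - 1L), function(i) {
    sel <- tt >= t_ic[i] & tt <= t_ic[i + 1L]
    if (sum(sel) < 3L) return(NA_real_)
    diff(range(disp[sel]))
  }, numeric(1))
}

#' Inverted-pendulum step length
#'
#' `L_step = 2 * sqrt(2 * L * h - h^2)`, where `L` is the pendulum length
#' (distance from the lower-back sensor to the ground) and `h` the per-step
#' change in height of the centre of mass.
#'
#' @param h per-step height change (m), `0 <= h < L`.
#' @param L pendulum length (m).
#' @return step length estimate (m), same length as `h`; `NA` inputs give
#'   `NA`.
#' @export
pendulum_step_length <- function(h, L) {
  if (L <= 0) stop("pendulum length L must be positive", call. = FALSE)
  bad <- !is.na(h) & (h < 0 | h >= L)
  if (any(bad)) {
    stop("step height h must satisfy 0 <= h < L for the pendulum model",
         call. = FALSE)
  }
  2 * sqrt(2 * L * h - h^2)
}

#' Calibrate the proportional correction constant K
#'
#' Ordinary least squares of the residual step length on shoe size:
#' `K = (S'S)^-1 S'(L_true - L_hat)`, fitted per speed condition.  The
#' units of K absorb the shoe-size convention (US, EU, metric...) used in
#' `S`: any convention works, but it must be the same convention used later
#' in [corrected_step_length()] and consistent across the calibration cohort.
#'
#' @param L_true gold-standard step lengths (m).
#' @param L_hat pendulum-model step lengths (m), same length.
#' @param S shoe sizes, same length, not all zero.
#' @return scalar K.
#' @export
calibrate_K <- function(L_true, L_hat, S) {
  if (length(L_true) != length(L_hat) || length(L_true) != length(S)) {
    stop("L_true, L_hat and S must have equal length", call. = FALSE)
  }
  if (length(S) < 2L) stop("need at least 2 calibration pairs", call. = FALSE)
  sts <- sum(S^2)
  if (sts == 0) stop("degenerate design: shoe sizes are all zero",
                     call. = FALSE)
  sum(S * (L_true - L_hat)) / sts
}

#' Corrected step length and step velocity
#'
#' `L_step(i) = 2 * sqrt(2 * L * h - h^2) + K * S`; step velocity is
#' `V_step(i) = L_step(i) / T_step(i)` when step times are supplied.
#'
#' @param h per-step height change (m).
#' @param L pendulum length (m).
#' @param K proportional constant for the speed condition (see
#'   [calibrate_K()]; shipped defaults were calibrated on a healthy cohort).
#' @param S the subject's shoe size, in the same convention used to
#'   calibrate `K`.
#' @param t_step optional per-step times (s) for the velocity.
#' @return list with `length` (m) and, when `t_step` is given, `velocity`
#'   (m/s).
#' @export
corrected_step_length <- function(h, L, K, S, t_step = NULL) {
  ls <- pendulum_step_length(h, L) + K * S
  out <- list(length = ls)
  if (!is.null(t_step)) {
    m <- min(length(ls), length(t_step))
    out$velocity <- ls[seq_len(m)] / t_step[seq_len(m)]
  }
  out
}

#' Step lengths and velocities for one walking trial
#'
#' Convenience wrapper: double drift-free integration of the vertical
#' acceleration, per-step heights at the detected contacts, pendulum model
#' and correction.
#'
#' @param av unfiltered gravity-removed vertical acceleration (m/s^2).
#' @param events a `gait_events` object.
#' @param fs sampling rate, Hz.
#' @param L pendulum length (m).
#' @param K correction constant for the condition.
#' @param S shoe size.
#' @param t0 time of the first sample of `av`.
#' @param hurst_cutoff drift threshold (see [emd_drift_free_integral()]).
#' @return list with `h`, `length`, `velocity`, `t_step`.
#' @export
trial_step_lengths <- function(av, events, fs, L, K, S, t0 = 0,
                               hurst_cutoff = 0.8) {
  if (length(events$t_ic) < 2L) {
    return(list(h = numeric(0), length = numeric(0), velocity = numeric(0),
                t_step = numeric(0)))
  }
  v <- emd_drift_free_integral(av, fs, hurst_cutoff)$y
  disp <- emd_drift_free_integral_series(v, fs, hurst_cutoff)
  h <- step_height(disp, events, fs, t0 = t0)
  t_step <- diff(events$t_ic)
  csl <- corrected_step_length(h, L, K, S, t_step = t_step)
  list(h = h, length = csl$length, velocity = csl$velocity, t_step = t_step)
}

# drift-free integral of an already-integrated series (same machinery)
emd_drift_free_integral_series <- function(v, fs, hurst_cutoff = 0.8) {
  emd_drift_free_integral(v, fs, hurst_cutoff)$y
}
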