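# Initial/end contact detection from preprocessed vertical acceleration,
# left/right assignment from low-passed yaw, and temporal gait parameters.

#' Dominant step frequency of a walking signal
#'
#' Frequency of maximum power spectral density of the (mean-subtracted)
#' series within `band`, from a zero-padded periodogram.  Used to set the
#' wavelet scales of the contact detector.
#'
#' @param x preprocessed vertical acceleration (m/s^2).
#' @param fs sampling rate, Hz.
#' @param band search band in Hz, default `c(0.5, 5)`.
#' @return dominant frequency in Hz.
#' @export
dominant_frequency <- function(x, fs, band = c(0.5, 5)) {
  n <- length(x)
  if (n < 2 * fs) {
    stop("need at least 2 s of signal to estimate the step frequency",
         call. = FALSE)
  }
  x <- x - mean(x)
  nfft <- max(4096L, 2^ceiling(log2(n)))
  P <- Mod(stats::fft(c(x, rep(0, nfft - n))))^2
  f <- (seq_len(nfft) - 1L) * fs / nfft
  keep <- f >= band[1L] & f <= band[2L]
  f[keep][which.max(P[keep])]
}

new_gait_events <- function(t_ic, t_ec, side = rep(NA_character_,
                                                   length(t_ic)),
                            f_dom = NA_real_, scale_ic = NA_real_,
                            scale_ec = NA_real_) {
  ev <- list(t_ic = t_ic, t_ec = t_ec, side = side, f_dom = f_dom,
             scale_ic = scale_ic, scale_ec = scale_ec)
  class(ev) <- "gait_events"
  ev
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf(
    "<gait_events> %d initial contacts, %d end contacts, f_dom = %.2f Hz\n",
    length(x$t_ic), length(x$t_ec), x$f_dom))
  invisible(x)
}

#' Export gait events as a data frame (`t_ic, t_ec, side`)
#' @param events a `gait_events` object.
#' @return data frame with one row per initial contact; `t_ec` is the paired
#'   (subsequent) end contact or `NA`.
#' @export
events_table <- function(events) {
  pair <- vapply(events$t_ic, function(ti) {
    nxt <- events$t_ec[events$t_ec > ti]
    if (length(nxt)) nxt[1L] else NA_real_
  }, numeric(1))
  data.frame(t_ic = events$t_ic, t_ec = pair, side = events$side)
}

#' Detect initial and end contacts by continuous wavelet transform
#'
#' The preprocessed vertical acceleration is cumulatively integrated
#' (trapezoid rule) and linearly detrended; a first smoothed differentiation
#' with the Gaussian wavelet (`gaus1`) gives a signal whose local minima are
#' initial-contact (IC) candidates; a second differentiation of that output
#' with the second-derivative ("Mexican hat") wavelet gives a signal whose
#' local maxima are end-contact (EC) candidates.  Wavelet scales follow
#' `scale = Fc * fs / f_dom` with the wavelet centre frequency Fc.  EC peaks
#' with magnitude at or below 20% of the mean peak magnitude are discarded;
#' the same relative gate (`ic_min_frac`) is applied to IC minima so that
#' noise-only stretches inside an analysis window (e.g. between TUG phases)
#' do not yield spurious contacts.  An IC lagging the previous retained IC by
#' less than 0.25 s or more than 2.25 s is discarded (greedy, left to right),
#' and events within `edge_guard_s` of the window boundary are dropped.
#'
#' @param av preprocessed (10 Hz low-passed, gravity-removed) vertical
#'   acceleration, m/s^2.
#' @param fs sampling rate, Hz.
#' @param f_dom dominant step frequency; estimated from `av` when `NULL`.
#' @param t0 time of the first sample (event times are `t0 + (i-1)/fs`).
#' @param config an [lg_config()].
#' @return a `gait_events` object (sides unassigned; see [assign_sides()]).
#'   If no IC survives, empty event vectors with a warning.
#' @export
detect_contacts <- function(av, fs, f_dom = NULL, t0 = 0,
                            config = lg_config()) {
  n <- length(av)
  empty <- function(msg) {
    warning(msg, call. = FALSE)
    new_gait_events(numeric(0), numeric(0), character(0))
  }
  if (n < 2 * fs) return(empty("window too short for contact detection"))
  if (stats::sd(av) == 0) return(empty("flat signal: no contacts found"))
  if (is.null(f_dom)) {
    f_dom <- dominant_frequency(av, fs, config$dom_freq_band)
  }
  scale_ic <- config$centre_freq_gaus1 * fs / f_dom
  scale_ec <- config$centre_freq_gaus2 * fs / f_dom

  v <- detrend_linear(cumtrapz_fs(av, fs))
  c1 <- cwt_gaus(v, scale_ic, order = 1)
  c2 <- cwt_gaus(c1, scale_ec, order = 2)

  guard <- ceiling(config$edge_guard_s * fs)
  in_window <- function(idx) idx[idx > guard & idx <= n - guard]

  # IC candidates: negative local minima of the first differentiation,
  # gated at ic_min_frac of the mean candidate depth.
  imin <- in_window(local_minima(c1))
  imin <- imin[c1[imin] < 0]
  if (length(imin) && config$ic_min_frac > 0) {
    depth <- -c1[imin]
    imin <- imin[depth > config$ic_min_frac * mean(depth)]
  }
  if (!length(imin)) return(empty("no initial contacts found"))

  # false-IC rule: greedy pruning on the lag to the previous retained IC
  lo <- config$ic_gap_s[1L]; hi <- config$ic_gap_s[2L]
  keep <- imin[1L]
  for (i in imin[-1L]) {
    lag <- (i - keep[length(keep)]) / fs
    if (lag >= lo && lag <= hi) keep <- c(keep, i)
  }
  t_ic <- t0 + (keep - 1L) / fs

  # EC candidates: positive local maxima of the second differentiation,
  # 20%-of-mean-peak magnitude rule.
  imax <- in_window(local_maxima(c2))
  imax <- imax[c2[imax] > 0]
  if (length(imax)) {
    mag <- c2[imax]
    imax <- imax[mag > config$ec_min_frac * mean(mag)]
  }
  t_ec <- t0 + (imax - 1L) / fs

  new_gait_events(t_ic, t_ec, f_dom = f_dom,
                  scale_ic = scale_ic, scale_ec = scale_ec)
}

#' Assign alternating side labels from low-passed yaw
#'
#' Side `"A"` is assigned where the 2 Hz low-passed yaw at the initial
#' contact is non-negative, `"B"` otherwise.  The trunk rotates towards
#' alternate sides on alternate steps, so labels should alternate; if more
#' than 20% of consecutive pairs violate alternation the labels are replaced
#' by forced alternation phased to agree with the majority of the yaw-based
#' labels.  The mapping of `{A, B}` to left/right is a configuration option
#' (`side_A_is`), since it depends on device mounting.
#'
#' @param events a `gait_events` object.
#' @param yaw_f low-passed yaw series covering the events (deg/s).
#' @param fs sampling rate of `yaw_f`, Hz.
#' @param t0 time of the first `yaw_f` sample.
#' @return `events` with the `side` field filled in.
#' @export
assign_sides <- function(events, yaw_f, fs, t0 = 0) {
  n_ic <- length(events$t_ic)
  if (!n_ic) return(events)
  tt <- t0 + (seq_along(yaw_f) - 1L) / fs
  yv <- interp_at(tt, yaw_f, events$t_ic)
  side <- ifelse(yv >= 0, "A", "B")
  if (n_ic >= 2L) {
    viol <- mean(side[-1L] == side[-n_ic])
    if (viol > 0.2) {
      altA <- rep_len(c("A", "B"), n_ic)
      altB <- rep_len(c("B", "A"), n_ic)
      side <- if (sum(side == altA) >= sum(side == altB)) altA else altB
    }
  }
  events$side <- side
  events
}

#' Temporal gait parameters from detected events
#'
#' Per-cycle stance, stride, step and swing times:
#' `TStance(i) = tEC(i+1) - tIC(i)`, `TStride(i) = tIC(i+2) - tIC(i)`,
#' `TStep(i) = tIC(i+1) - tIC(i)`, `TSwing(i) = TStride(i) - TStance(i)`
#' (the swing identity holds exactly by construction).  Step count is the
#' number of initial contacts.
#'
#' @param events a `gait_events` object.
#' @return list with numeric vectors `t_stance, t_stride, t_step, t_swing`,
#'   the per-cycle `side`, and `n_steps`.  With fewer than 3 ICs or 2 ECs the
#'   parameter vectors are empty.
#' @export
temporal_params <- function(events) {
  t_ic <- events$t_ic
  t_ec <- events$t_ec
  n_ic <- length(t_ic)
  n_steps <- n_ic
  if (n_ic < 3L || length(t_ec) < 2L) {
    return(list(t_stance = numeric(0), t_stride = numeric(0),
                t_step = numeric(0), t_swing = numeric(0),
                side = character(0), n_steps = n_steps))
  }
  n_cyc <- n_ic - 2L
  t_stride <- t_ic[3:n_ic] - t_ic[1:n_cyc]
  t_step <- t_ic[2:(n_cyc + 1L)] - t_ic[1:n_cyc]
  t_stance <- rep(NA_real_, n_cyc)
  m <- min(n_cyc, length(t_ec) - 1L)
  if (m > 0L) t_stance[1:m] <- t_ec[2:(m + 1L)] - t_ic[1:m]
  t_swing <- t_stride - t_stance
  list(t_stance = t_stance, t_stride = t_stride, t_step = t_step,
       t_swing = t_swing, side = events$side[1:n_cyc], n_steps = n_steps)
}
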