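# Timed Up and Go phase segmentation (db5 wavelet approximations of pitch
# and yaw) and per-phase features.

new_tug_phases <- function(df) {
  class(df) <- c("tug_phases", "data.frame")
  df
}

#' @export
print.tug_phases <- function(x, ...) {
  cat("<tug_phases>\n")
  print.data.frame(x)
  invisible(x)
}

#' Segment a Timed Up and Go trial into its five phases
#'
#' Sit-to-stand (STS) and stand-to-sit (StS) are found on the level-5 db5
#' approximation of pitch velocity: STS is the interval around the largest
#' pitch extremum before the first turn, StS around the largest after the
#' second turn; within each, landmark `ii` is the extremum and `i`/`iii` are
#' the flanking crossings of 10% of the extremum amplitude.  The two turns
#' are found on the level-2 approximation of yaw: the two longest intervals
#' where its magnitude exceeds 15% of the global maximum, with `ii` at each
#' interval's magnitude maximum.  Walking phases are the gaps
#' sit-to-stand -> turn 1 and turn 1 -> turn 2.
#'
#' @param pitch pitch angular velocity (deg/s).
#' @param yaw yaw angular velocity (deg/s).
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample.
#' @param config an [lg_config()].
#' @return a `tug_phases` data frame with columns `phase`
#'   (`STS, WALK1, TURN1, WALK2, TURN2, StS`), `t_i`, `t_ii`, `t_iii`.
#' @export
detect_phases <- function(pitch, yaw, fs, t0 = 0, config = lg_config()) {
  n <- length(pitch)
  tt <- t0 + (seq_len(n) - 1L) / fs
  pA <- dwt_approximation(pitch, config$tug_pitch_level)
  yA <- dwt_approximation(yaw, config$tug_yaw_level)

  # --- turns from |yaw_A2| ---
  ym <- abs(yA)
  thr <- config$tug_turn_frac * max(ym)
  above <- ym > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) < 2L) {
    stop(sprintf(
      "TUG segmentation failed: found %d yaw interval(s) above threshold, need 2",
      nrow(runs)), call. = FALSE)
  }
  runs$len <- runs$end - runs$start + 1L
  turns <- runs[order(-runs$len)[1:2], ]
  turns <- turns[order(turns$start), ]
  turn_lm <- lapply(seq_len(2L), function(k) {
    i0 <- turns$start[k]; i1 <- turns$end[k]
    ii <- i0 - 1L + which.max(ym[i0:i1])
    c(t_i = tt[i0], t_ii = tt[ii], t_iii = tt[i1])
  })

  # --- sit-to-stand / stand-to-sit from pitch_A5 ---
  find_burst <- function(idx_range) {
    seg <- pA[idx_range]
    ii_rel <- which.max(abs(seg))
    ii <- idx_range[1L] - 1L + ii_rel
    peak <- pA[ii]
    if (abs(peak) < config$tug_min_pitch_peak) {
      stop(sprintf(
        "TUG segmentation failed: pitch extremum %.1f deg/s below the %.1f deg/s floor",
        abs(peak), config$tug_min_pitch_peak), call. = FALSE)
    }
    lev <- config$tug_amp_frac * abs(peak)
    sgn <- sign(peak)
    below <- sgn * pA < lev            # signal fallen under 10% of extremum
    i_lo <- ii
    while (i_lo > 1L && !below[i_lo - 1L]) i_lo <- i_lo - 1L
    i_hi <- ii
    while (i_hi < n && !below[i_hi + 1L]) i_hi <- i_hi + 1L
    c(t_i = tt[i_lo], t_ii = tt[ii], t_iii = tt[i_hi])
  }
  t1_start_idx <- which(tt >= turn_lm[[1L]][["t_i"]])[1L]
  t2_peak_idx <- which(tt >= turn_lm[[2L]][["t_ii"]])[1L]
  sts_lm <- find_burst(seq_len(max(t1_start_idx - 1L, 2L)))
  sit <- find_burst(seq(min(t2_peak_idx, n - 1L), n))

  ph <- new_tug_phases(data.frame(
    phase = c("STS", "WALK1", "TURN1", "WALK2", "TURN2", "StS"),
    t_i = c(sts_lm[["t_i"]],
            sts_lm[["t_iii"]], turn_lm[[1L]][["t_i"]],
            turn_lm[[1L]][["t_iii"]], turn_lm[[2L]][["t_i"]],
            sit[["t_i"]]),
    t_ii = c(sts_lm[["t_ii"]],
             (sts_lm[["t_iii"]] + turn_lm[[1L]][["t_i"]]) / 2,
             turn_lm[[1L]][["t_ii"]],
             (turn_lm[[1L]][["t_iii"]] + turn_lm[[2L]][["t_i"]]) / 2,
             turn_lm[[2L]][["t_ii"]], sit[["t_ii"]]),
    t_iii = c(sts_lm[["t_iii"]],
              turn_lm[[1L]][["t_i"]], turn_lm[[1L]][["t_iii"]],
              turn_lm[[2L]][["t_i"]], turn_lm[[2L]][["t_iii"]],
              sit[["t_iii"]]),
    stringsAsFactors = FALSE))
  ord <- ph$t_i
  if (is.unsorted(ord[c(1, 2, 3, 4, 5)]) || ph$t_i[6L] < ph$t_ii[5L]) {
    stop("TUG segmentation failed: phases out of order", call. = FALSE)
  }
  ph
}

# registry-ordered TUG feature names for one sit phase (13 features)
tug_sit_feature_names <- function() {
  c("Range Pitch Vel (i-ii)", "Range Pitch Vel (ii-iii)",
    "SD Pitch Vel (i-iii)", "Mean Pitch Vel (i-iii)",
    "Median Pitch Vel (i-iii)", "Max Pitch Vel (i-ii)",
    "Max Pitch Vel (ii-iii)", "Mean Pitch Acc (i-ii)",
    "Mean Pitch Acc (ii-iii)", "Mean Acc AP (i-iii)", "SD Acc AP (i-iii)",
    "Median Acc AP (i-iii)", "Duration (i-iii)")
}

tug_turn_feature_names <- function() {
  c("N Steps", "Max Yaw Vel", "Mean Yaw Acc (i-ii)", "Mean Yaw Acc (ii-iii)",
    "Duration")
}

tug_walk_feature_names <- function() {
  c("RMS Acc AP", "RMS Acc ML", "RMS Acc V", "Mean Step Time",
    "SD Step Time", "N Steps", "Duration")
}

#' Gait events for a segmented Timed Up and Go trial
#'
#' Runs the contact detector separately within each walking and turning
#' window and merges the results.  Per-bout detection matters because the
#' false-contact rule (a contact more than 2.25 s after the previous one is
#' discarded) would otherwise cascade across the turn gap and erase the
#' second walking bout.
#'
#' @param sig an `"aligned_signal"` with walking filters (see
#'   [preprocess_trial()]).
#' @param phases a `tug_phases` data frame.
#' @param config an [lg_config()].
#' @return a merged `gait_events` object (times sorted; sides unassigned).
#' @export
tug_gait_events <- function(sig, phases, config = lg_config()) {
  fs <- attr(sig, "fs")
  t_ic <- numeric(0); t_ec <- numeric(0)
  for (ph in c("WALK1", "TURN1", "WALK2", "TURN2")) {
    i <- which(phases$phase == ph)
    if (!length(i)) next
    sel <- sig$t >= phases$t_i[i] & sig$t <= phases$t_iii[i]
    if (sum(sel) < 3L) next
    av <- sig$aV_f %||% sig$aV
    ev <- withCallingHandlers(
      detect_contacts(av[sel], fs, t0 = sig$t[sel][1L], config = config),
      warning = function(w) invokeRestart("muffleWarning"))
    t_ic <- c(t_ic, ev$t_ic)
    t_ec <- c(t_ec, ev$t_ec)
  }
  new_gait_events(sort(t_ic), sort(t_ec))
}

#' Per-phase Timed Up and Go features
#'
#' Computes the 43 registry features for one TUG trial: 13 each for
#' sit-to-stand and stand-to-sit (pitch-velocity statistics over the stage
#' windows `i-ii`, `ii-iii`, `i-iii`, the mean angular acceleration
#' `delta-velocity / delta-t` across each stage, AP-acceleration statistics
#' and duration), 5 each for the two turns (step count, maximum yaw
#' magnitude, stage mean yaw accelerations of the magnitude signal,
#' duration), and 7 for the pooled walking phases (RMS accelerations, step
#' time statistics and step count from the gait events restricted to the
#' walk windows, and total walk duration).
#'
#' @param sig an `"aligned_signal"` covering the trial (with walking filters;
#'   see [preprocess_trial()]).
#' @param phases a `tug_phases` data frame (see [detect_phases()]).
#' @param events a `gait_events` object for the trial (detected on the
#'   walking span); used for step counts and step times.
#' @return named numeric vector of length 43 with names
#'   `"<PHASE>: <feature>"`; features of a missing phase are `NA`.
#' @export
tug_features <- function(sig, phases, events) {
  fs <- attr(sig, "fs")
  tt <- sig$t
  win <- function(t_a, t_b) tt >= t_a & tt <= t_b
  at_t <- function(x, tq) interp_at(tt, x, tq)
  row_of <- function(ph) {
    i <- which(phases$phase == ph)
    if (length(i)) phases[i, ] else NULL
  }
  out <- numeric(0)

  for (ph in c("STS", "StS")) {
    p <- row_of(ph)
    nm <- paste0(ph, ": ", tug_sit_feature_names())
    if (is.null(p)) {
      out <- c(out, stats::setNames(rep(NA_real_, 13L), nm)); next
    }
    w1 <- win(p$t_i, p$t_ii); w2 <- win(p$t_ii, p$t_iii)
    w  <- win(p$t_i, p$t_iii)
    pv <- sig$pitch
    vals <- c(
      diff(range(pv[w1])), diff(range(pv[w2])),
      stats::sd(pv[w]), mean(pv[w]), stats::median(pv[w]),
      max(pv[w1]), max(pv[w2]),
      (at_t(pv, p$t_ii) - at_t(pv, p$t_i)) / (p$t_ii - p$t_i),
      (at_t(pv, p$t_iii) - at_t(pv, p$t_ii)) / (p$t_iii - p$t_ii),
      mean(sig$aAP[w]), stats::sd(sig$aAP[w]), stats::median(sig$aAP[w]),
      p$t_iii - p$t_i)
    out <- c(out, stats::setNames(vals, nm))
  }

  for (ph in c("TURN1", "TURN2")) {
    p <- row_of(ph)
    nm <- paste0(ph, ": ", tug_turn_feature_names())
    if (is.null(p)) {
      out <- c(out, stats::setNames(rep(NA_real_, 5L), nm)); next
    }
    w <- win(p$t_i, p$t_iii)
    ym <- abs(sig$yaw)
    n_steps <- sum(events$t_ic > p$t_i & events$t_ic < p$t_iii)
    vals <- c(
      n_steps, max(ym[w]),
      (at_t(ym, p$t_ii) - at_t(ym, p$t_i)) / (p$t_ii - p$t_i),
      (at_t(ym, p$t_iii) - at_t(ym, p$t_ii)) / (p$t_iii - p$t_ii),
      p$t_iii - p$t_i)
    out <- c(out, stats::setNames(vals, nm))
  }

  w1p <- row_of("WALK1"); w2p <- row_of("WALK2")
  nm <- paste0("WALK: ", tug_walk_feature_names())
  if (is.null(w1p) && is.null(w2p)) {
    out <- c(out, stats::setNames(rep(NA_real_, 7L), nm))
  } else {
    wsel <- rep(FALSE, length(tt))
    dur <- 0
    step_times <- numeric(0)
    n_steps <- 0L
    for (p in list(w1p, w2p)) {
      if (is.null(p)) next
      wsel <- wsel | win(p$t_i, p$t_iii)
      dur <- dur + (p$t_iii - p$t_i)
      ics <- events$t_ic[events$t_ic >= p$t_i & events$t_ic <= p$t_iii]
      n_steps <- n_steps + length(ics)
      if (length(ics) >= 2L) step_times <- c(step_times, diff(ics))
    }
    aAP <- sig$aAP_f %||% sig$aAP
    aML <- sig$aML_f %||% sig$aML
    aV  <- sig$aV_f %||% sig$aV
    rms <- function(x) sqrt(mean(x^2))
    vals <- c(rms(aAP[wsel]), rms(aML[wsel]), rms(aV[wsel]),
              if (length(step_times)) mean(step_times) else NA_real_,
              if (length(step_times) >= 2L) stats::sd(step_times)
              else NA_real_,
              n_steps, dur)
    out <- c(out, stats::setNames(vals, nm))
  }
  out
}

# data-frame access of a possibly missing column
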