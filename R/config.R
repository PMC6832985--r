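#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters used across the pipeline, with
#' the defaults used for the healthy-adult protocol.  Any entry can be
#' overridden by passing a named list to `lg_config()`.
#'
#' @param ... named overrides, e.g. `lg_config(lowpass_walk_hz = 8)`.
#' @return a named list of class `"lg_config"`.
#' @details
#' Key entries:
#' \describe{
#'   \item{fs}{nominal sampling rate, Hz (31.25 for the reference sensor).}
#'   \item{gravity}{gravitational constant used to convert g to m/s^2 (9.81).}
#'   \item{lowpass_walk_hz, lowpass_walk_order}{zero-phase Butterworth low-pass
#'     applied to accelerations for walking tests (10 Hz, order 4).}
#'   \item{yaw_lowpass_hz}{low-pass for the yaw channel used in left/right
#'     assignment (2 Hz, order 4).}
#'   \item{centre_freq_gaus1, centre_freq_gaus2}{wavelet centre frequencies
#'     used by the scale rule `scale = Fc * fs / f_dom` (0.2 and 0.3, the
#'     conventional values for the first and second Gaussian-derivative
#'     wavelets).}
#'   \item{ic_gap_s}{admissible lag range between consecutive initial
#'     contacts; candidates within 0.25 s or beyond 2.25 s of the previous
#'     retained contact are discarded.}
#'   \item{ec_min_frac}{end-contact peaks below this fraction of the mean peak
#'     magnitude are discarded (0.2).}
#'   \item{ic_min_frac}{same relative gate applied to initial-contact minima
#'     (0.2); set to 0 to disable and keep every local minimum.}
#'   \item{edge_guard_s}{events closer than this to the analysis window
#'     boundary are discarded (0.25 s, wavelet edge effects).}
#'   \item{hurst_cutoff}{intrinsic mode functions with Hurst exponent above
#'     this are treated as drift and removed (0.8).}
#'   \item{K}{named vector of step-length correction constants per speed
#'     condition; the shipped values (SSV 1.13, FV 1.50) were calibrated on a
#'     healthy cohort and do not generalize to impaired gait -- recalibrate
#'     with [calibrate_K()] for any new population.}
#'   \item{ellipse_coverage}{coverage probability of the sway ellipse (0.95).}
#'   \item{tug_pitch_level, tug_yaw_level}{db5 approximation levels for the
#'     sit-to-stand/stand-to-sit (5) and turn (2) detectors.}
#'   \item{tug_turn_frac}{turn intervals are where the yaw approximation
#'     magnitude exceeds this fraction of its maximum (0.15).}
#'   \item{tug_amp_frac}{phase start/end landmarks are the crossings of this
#'     fraction of the phase extremum amplitude (0.10).}
#'   \item{tug_min_pitch_peak}{minimum pitch-approximation extremum (deg/s)
#'     for a sit-to-stand/stand-to-sit to count as detected (10).}
#'   \item{gyro_map}{mapping from sensor gyro channels to anatomical pitch
#'     (about the mediolateral axis) and yaw (about the vertical axis), with
#'     signs; device-orientation dependent.}
#'   \item{side_A_is}{which foot the abstract side label "A" denotes
#'     ("left" or "right"); sign convention of the yaw-based assignment.}
#' }
#' @export
#' @examples
#' cfg <- lg_config(lowpass_walk_hz = 8)
#' cfg$lowpass_walk_hz
lg_config <- function(...) {
  cfg <- list(
    fs                 = 31.25,
    gravity            = 9.81,
    lowpass_walk_hz    = 10,
    lowpass_walk_order = 4,
    yaw_lowpass_hz     = 2,
    yaw_lowpass_order  = 4,
    centre_freq_gaus1  = 0.2,
    centre_freq_gaus2  = 0.3,
    dom_freq_band      = c(0.5, 5),
    ic_gap_s           = c(0.25, 2.25),
    ec_min_frac        = 0.2,
    ic_min_frac        = 0.2,
    edge_guard_s       = 0.25,
    hurst_cutoff       = 0.8,
    K                  = c(SSV = 1.13, FV = 1.50),
    ellipse_coverage   = 0.95,
    ellipse_method     = "chisq",
    jerk_aggregate     = "rms",
    tug_pitch_level    = 5L,
    tug_yaw_level      = 2L,
    tug_turn_frac      = 0.15,
    tug_amp_frac       = 0.10,
    tug_min_pitch_peak = 10,
    gyro_map           = list(pitch = "gx", yaw = "gy",
                              pitch_sign = 1, yaw_sign = 1),
    side_A_is          = "right",
    per_leg_output     = FALSE,
    strict_registry    = FALSE
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "lg_config"
  cfg
}
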