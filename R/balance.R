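# Static postural balance features: spectral, time-domain and 95%-ellipse.

#' Spectral sway features (F50%, F95%, spectral centroid)
#'
#' One-sided periodogram of the mean-subtracted series over `(0, fs/2]`
#' (rectangular window, DC excluded).  `F50`/`F95` are the smallest
#' frequencies at which the cumulative power reaches 50%/95% of the total;
#' the spectral centroid is `sum(f * P) / sum(P)`.
#'
#' @param x series (zero mean is enforced internally).
#' @param fs sampling rate, Hz.
#' @return named numeric `c(F50, F95, SC)` in Hz; all `NA` for an all-zero
#'   signal.
#' @export
spectral_features <- function(x, fs) {
  x <- x - mean(x)
  if (all(x == 0)) {
    return(c(F50 = NA_real_, F95 = NA_real_, SC = NA_real_))
  }
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  half <- seq(2L, floor(n / 2) + 1L)      # DC excluded
  f <- (half - 1L) * fs / n
  P <- P[half]
  cp <- cumsum(P) / sum(P)
  c(F50 = f[which(cp >= 0.50)[1L]],
    F95 = f[which(cp >= 0.95)[1L]],
    SC  = sum(f * P) / sum(P))
}

#' Time-domain sway features
#'
#' On the mean-subtracted series: maximum and mean absolute acceleration,
#' RMS, jerk (RMS of the central-difference derivative), mean sway velocity
#' (mean absolute drift-free integral, via [emd_drift_free_integral()]) and
#' the total acceleration path (sum of absolute successive differences).
#'
#' @param x acceleration series (m/s^2).
#' @param fs sampling rate, Hz.
#' @return named numeric `c(MaxAcc, MeanAcc, RMS, Jerk, SwayV, SPathA)`.
#' @export
time_features <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  if (all(x == 0)) {
    return(c(MaxAcc = 0, MeanAcc = 0, RMS = 0, Jerk = 0, SwayV = 0,
             SPathA = 0))
  }
  d <- (x[c(2:n, n)] - x[c(1L, 1:(n - 1L))]) * fs / 2   # central difference
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  sway_v <- emd_drift_free_integral(x, fs)$y
  c(MaxAcc  = max(abs(x)),
    MeanAcc = mean(abs(x)),
    RMS     = sqrt(mean(x^2)),
    Jerk    = sqrt(mean(d^2)),
    SwayV   = mean(abs(sway_v)),
    SPathA  = sum(abs(diff(x))))
}

#' 95% sway ellipse from the AP/ML covariance
#'
#' Eigendecomposition of the 2x2 sample covariance of the (mean-subtracted)
#' anteroposterior and mediolateral accelerations.  Semi-axes are
#' `sqrt(chi^2_2(coverage) * lambda_i)`, the area is `pi * a1 * a2`, and each
#' anatomical axis is matched to the eigenvector closest to it: the reported
#' axis length is the full axis `2 * a_i` of that eigenvector and the angle
#' (degrees, in (-90, 90]) is between the eigenvector and the anatomical
#' axis.
#'
#' @param aAP,aML equal-length acceleration series (m/s^2).
#' @param coverage coverage probability (default 0.95).
#' @return named numeric `c(EllipseArea, EllipseAxis_AP, EllipseAxis_ML,
#'   EllipseAngle_AP, EllipseAngle_ML)` (area in m^2/s^4, axes in m/s^2,
#'   angles in degrees).
#' @export
ellipse_features <- function(aAP, aML, coverage = 0.95) {
  if (length(aAP) != length(aML)) {
    stop("aAP and aML must have equal length", call. = FALSE)
  }
  if (length(aAP) < 10L) {
    stop("need at least 10 samples for the sway ellipse", call. = FALSE)
  }
  X <- cbind(AP = aAP - mean(aAP), ML = aML - mean(aML))
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (lam[2L] <= .Machine$double.eps * lam[1L]) {
    warning("rank-deficient sway covariance: degenerate ellipse")
  }
  q <- stats::qchisq(coverage, df = 2)
  semi <- sqrt(q * lam)
  # eigenvectors in (AP, ML) coordinates; match each anatomical axis to the
  # eigenvector with the larger |cosine| to it
  v1 <- e$vectors[, 1L]    # major
  ap_gets_major <- abs(v1[1L]) >= abs(v1[2L])
  idx_ap <- if (ap_gets_major) 1L else 2L
  idx_ml <- if (ap_gets_major) 2L else 1L
  ang <- function(v, axis) {
    a <- rad2deg(atan2(v[2L], v[1L]))          # angle from AP axis
    if (axis == "ML") a <- a - 90
    a <- ((a + 90) %% 180) - 90                # fold to (-90, 90]
    if (a == -90) a <- 90
    a
  }
  c(EllipseArea     = pi * semi[1L] * semi[2L],
    EllipseAxis_AP  = 2 * semi[idx_ap],
    EllipseAxis_ML  = 2 * semi[idx_ml],
    EllipseAngle_AP = ang(e$vectors[, idx_ap], "AP"),
    EllipseAngle_ML = ang(e$vectors[, idx_ml], "ML"))
}

#' All 23 balance features for one static condition
#'
#' Computes the full feature set for one Berg Balance Scale static standing
#' condition from the unfiltered, gravity-removed AP/ML accelerations:
#' per-axis F50%, F95%, SC, Max/Mean/RMS acceleration, ellipse angle and
#' axis, jerk, sway velocity and acceleration path, plus the scalar 95%
#' ellipse area.
#'
#' @param sig an `"aligned_signal"` restricted to the annotated condition
#'   window.
#' @param condition condition label (`"SU"`, `"SEC"`, `"SFT"`, `"ST"`,
#'   `"SOL"`); recorded in the output only.
#' @param config an [lg_config()].
#' @return named numeric vector of length 23; names match the feature
#'   registry.  A window shorter than 5 s yields all-`NA` values with a
#'   warning.
#' @export
bbs_condition_features <- function(sig, condition = "SU",
                                   config = lg_config()) {
  fs <- attr(sig, "fs") %||% config$fs
  nm <- bbs_feature_names()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (nrow(sig) < 5 * fs) {
    warning(sprintf("condition %s window shorter than 5 s: skipped",
                    condition))
    return(out)
  }
  for (axis in c("AP", "ML")) {
    x <- if (axis == "AP") sig$aAP else sig$aML
    sp <- spectral_features(x, fs)
    td <- time_features(x, fs)
    out[paste0("F50% ", axis)] <- sp[["F50"]]
    out[paste0("F95% ", axis)] <- sp[["F95"]]
    out[paste0("SC ", axis)] <- sp[["SC"]]
    out[paste0("Max Acc ", axis)] <- td[["MaxAcc"]]
    out[paste0("Mean Acc ", axis)] <- td[["MeanAcc"]]
    out[paste0("RMS ", axis)] <- td[["RMS"]]
    out[paste0("Jerk ", axis)] <- td[["Jerk"]]
    out[paste0("SwayV ", axis)] <- td[["SwayV"]]
    out[paste0("SPathA ", axis)] <- td[["SPathA"]]
  }
  el <- ellipse_features(sig$aAP, sig$aML, config$ellipse_coverage)
  out["95% Ellipse Area"] <- el[["EllipseArea"]]
  out["Ellipse Axis AP"] <- el[["EllipseAxis_AP"]]
  out["Ellipse Axis ML"] <- el[["EllipseAxis_ML"]]
  out["Ellipse Angle AP"] <- el[["EllipseAngle_AP"]]
  out["Ellipse Angle ML"] <- el[["EllipseAngle_ML"]]
  out
}

# canonical order of the 23 per-condition balance feature names
bbs_feature_names <- function() {
  per_axis <- function(axis) {
    paste0(c("F50% ", "F95% ", "SC ", "Max Acc ", "Mean Acc ", "RMS ",
             "Ellipse Angle ", "Ellipse Axis ", "Jerk ", "SwayV ",
             "SPathA "), axis)
  }
  c(per_axis("AP"), per_axis("ML"), "95% Ellipse Area")
}
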