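# Wavelet primitives: Gaussian-derivative CWT (gait events) and a db5
# multiresolution approximation (TUG segmentation).

#' Continuous wavelet transform with a Gaussian-derivative wavelet
#'
#' Convolves the series with the first (`order = 1`) or second (`order = 2`)
#' derivative of a Gaussian of standard deviation `scale` samples, i.e. a
#' smoothed differentiation.  The kernel is the true derivative of a
#' unit-area Gaussian, so on a unit ramp the order-1 output is +1 and on
#' `t^2/2` the order-2 output is +1: extrema of the output are extrema of the
#' smoothed derivative, which is what the contact detector needs.  The series
#' is reflection-padded, making the operation zero-phase.
#'
#' @param x numeric series.
#' @param scale wavelet scale in samples (Gaussian standard deviation).
#' @param order derivative order, 1 or 2.
#' @return numeric series of the same length.
#' @export
cwt_gaus <- function(x, scale, order = 1) {
  stopifnot(order %in% c(1, 2), scale > 0)
  T <- ceiling(5 * scale)
  tau <- seq(-T, T)
  G <- exp(-tau^2 / (2 * scale^2)) / (sqrt(2 * pi) * scale)
  w <- if (order == 1) {
    -tau / scale^2 * G
  } else {
    (tau^2 / scale^4 - 1 / scale^2) * G
  }
  # stats::filter computes a sliding correlation; correlating with the
  # time-reversed kernel is the convolution we want, and reversing the odd
  # (order-1) kernel flips its sign -- pass w unreversed and it comes out as
  # the true smoothed derivative (checked on ramp / parabola: +1).
  xp <- reflect_pad(x, T)
  y <- stats::filter(xp, w, method = "convolution", sides = 2)
  as.numeric(y[(T + 1L):(T + length(x))])
}

# Daubechies extremal-phase scaling filters (decomposition low-pass,
# unit-energy convention after /sqrt(2)).  Standard published constants.
.db_filters <- list(
  db5 = c(0.0033357252854737712, -0.012580751999081999,
          -0.006241490212798274,  0.07757149384004572,
          -0.032244869584638375, -0.24229488706638203,
           0.13842814590132074,   0.7243085284377729,
           0.6038292697971896,    0.16010239797419293)
)

#' Reconstruction of a series from its level-J wavelet approximation
#'
#' Computes the multiresolution approximation `A_J` of a series with a
#' Daubechies wavelet: the reconstruction from the level-`level`
#' approximation coefficients with all detail coefficients zeroed.  A maximal
#' overlap (undecimated) transform is used so the output has the same length
#' as the input and is free of decimation phase; the series is mirror-extended
#' before the circular transform to suppress wrap-around edge artifacts.
#' The approximation passband is roughly below `fs / 2^(level+1)`.
#'
#' @param x numeric series.
#' @param level decomposition level (J >= 1).
#' @param wavelet filter name; `"db5"`.
#' @return numeric series of the same length as `x`.
#' @export
dwt_approximation <- function(x, level, wavelet = "db5") {
  g <- .db_filters[[wavelet]]
  if (is.null(g)) stop("unknown wavelet: ", wavelet, call. = FALSE)
  g <- g / sqrt(2)           # MODWT unit-energy scaling filter
  L <- length(g)
  n <- length(x)
  if (n < 2^level * L) {
    stop(sprintf("series too short for level %d (need >= %d samples, have %d)",
                 level, 2^level * L, n), call. = FALSE)
  }
  # mirror extension, then circular pyramid
  xe <- c(x, rev(x))
  N <- length(xe)
  v <- xe
  for (j in seq_len(level)) {
    step <- 2^(j - 1L)
    vj <- numeric(N)
    idx0 <- seq_len(N) - 1L
    for (l in seq_len(L)) {
      shift <- (l - 1L) * step
      vj <- vj + g[l] * v[((idx0 - shift) %% N) + 1L]
    }
    v <- vj
  }
  # ascend with the adjoint filters (details are zero)
  a <- v
  for (j in rev(seq_len(level))) {
    step <- 2^(j - 1L)
    aj <- numeric(N)
    idx0 <- seq_len(N) - 1L
    for (l in seq_len(L)) {
      shift <- (l - 1L) * step
      aj <- aj + g[l] * a[((idx0 + shift) %% N) + 1L]
    }
    a <- aj
  }
  a[seq_len(n)]
}
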