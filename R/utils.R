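# Internal numeric helpers shared across modules.

#' Cumulative trapezoidal integral of a uniformly sampled series
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @return numeric series of the same length, starting at 0.
#' @keywords internal
#' @noRd
cumtrapz_fs <- function(x, fs) {
  if (length(x) < 2L) return(rep(0, length(x)))
  as.numeric(pracma::cumtrapz(seq_along(x) / fs, x))
}

# Remove the least-squares linear trend.
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 3L) return(x - mean(x))
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), x)
  x - fit$fitted.values
}

# Indices of strict local minima / maxima (interior points).
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] < x[i - 1L] & x[i] <= x[i + 1L]]
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

# Reflect-pad a series by k samples on both ends.
reflect_pad <- function(x, k) {
  n <- length(x)
  k <- min(k, n - 1L)
  c(x[(k + 1L):2L], x, x[(n - 1L):(n - k)])
}

# Linear interpolation of a series sampled at t onto times tq (no extrapolation
# beyond range; clamped).
interp_at <- function(t, x, tq) {
  tq <- pmin(pmax(tq, t[1L]), t[length(t)])
  stats::approx(t, x, xout = tq, rule = 2)$y
}

# deg <-> rad
deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a
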