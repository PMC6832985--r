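# Empirical mode decomposition, rescaled-range Hurst exponent, and the
# drift-free cumulative integral used for vertical velocity/displacement and
# sway velocity.

#' Empirical mode decomposition
#'
#' Standard sifting with cubic-spline envelopes through the local extrema.
#' End effects are curbed by mirroring the two extrema nearest each boundary.
#' Sifting stops on a Cauchy-type criterion
#' (`sum((h - h_new)^2) / sum(h^2) < tol`) or after `max_sift` iterations;
#' decomposition stops when the residue has fewer than 4 extrema or
#' `max_imf` intrinsic mode functions have been extracted.
#'
#' @param x numeric series.
#' @param max_imf maximum number of intrinsic mode functions.
#' @param tol Cauchy stopping tolerance for sifting.
#' @param max_sift maximum sifting iterations per IMF.
#' @return list with `imf` (matrix, one IMF per column; may have 0 columns)
#'   and `residue`.
#' @export
emd_decompose <- function(x, max_imf = 12L, tol = 0.2, max_sift = 50L) {
  n <- length(x)
  imfs <- list()
  r <- x

  envelope <- function(idx, val, boundary_n) {
    # mirror up to 2 extrema about each boundary, then cubic spline
    k <- length(idx)
    pre_i <- 2 - rev(idx[seq_len(min(2L, k))])          # 2*1 - idx
    pre_v <- rev(val[seq_len(min(2L, k))])
    post_i <- 2L * boundary_n - rev(idx[(k - min(2L, k) + 1L):k])
    post_v <- rev(val[(k - min(2L, k) + 1L):k])
    xi <- c(pre_i, idx, post_i)
    yi <- c(pre_v, val, post_v)
    o <- order(xi)
    xi <- xi[o]; yi <- yi[o]
    dup <- duplicated(xi)
    stats::spline(xi[!dup], yi[!dup], xout = seq_len(boundary_n),
                  method = "fmm")$y
  }

  repeat {
    h <- r
    for (s in seq_len(max_sift)) {
      imax <- local_maxima(h)
      imin <- local_minima(h)
      if (length(imax) < 2L || length(imin) < 2L) break
      up <- envelope(imax, h[imax], n)
      lo <- envelope(imin, h[imin], n)
      m <- (up + lo) / 2
      h_new <- h - m
      crit <- sum((h - h_new)^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      if (crit < tol) break
    }
    imax <- local_maxima(h); imin <- local_minima(h)
    if (length(imax) < 2L || length(imin) < 2L) break
    imfs[[length(imfs) + 1L]] <- h
    r <- r - h
    if (length(imfs) >= max_imf) break
    if (length(local_maxima(r)) + length(local_minima(r)) < 4L) break
  }
  imf <- if (length(imfs)) do.call(cbind, imfs) else
    matrix(numeric(0), nrow = n, ncol = 0)
  list(imf = imf, residue = r)
}

#' Hurst exponent by rescaled-range analysis
#'
#' Corrected rescaled-range (R/S) estimate: block R/S statistics over
#' log-spaced window sizes are compared with their small-sample white-noise
#' expectation (Anis-Lloyd-Peters), and the exponent is `0.5` plus the slope
#' of the log-deviation -- near 0.5 for white noise, near 1 for trends, near
#' 0 for strongly anti-persistent series.  A constant series returns 1.0 by
#' convention (a pure trend).  The result is clipped to `[0, 1.2]`.
#'
#' @param x numeric series (length >= 64 recommended).
#' @return Hurst exponent estimate.
#' @export
hurst_exponent <- function(x) {
  n <- length(x)
  if (n < 16L) stop("series too short for a Hurst estimate", call. = FALSE)
  if (stats::sd(x) == 0) return(1.0)

  rs_expected <- function(m) {
    # E[R/S] for iid Gaussian blocks of length m (Anis-Lloyd, Peters form)
    i <- seq_len(m - 1L)
    s <- sum(sqrt((m - i) / i))
    if (m <= 340) {
      g <- exp(lgamma((m - 1) / 2) - lgamma(m / 2)) / sqrt(pi)
      g * s
    } else {
      s / sqrt(m * pi / 2)
    }
  }

  sizes <- unique(round(exp(seq(log(8), log(n %/% 2), length.out = 10))))
  sizes <- sizes[sizes >= 8]
  rs <- rep(NA_real_, length(sizes))
  for (k in seq_along(sizes)) {
    m <- sizes[k]
    nb <- n %/% m
    vals <- numeric(0)
    for (b in seq_len(nb)) {
      seg <- x[((b - 1L) * m + 1L):(b * m)]
      s <- stats::sd(seg)
      if (s == 0) next
      d <- cumsum(seg - mean(seg))
      vals <- c(vals, (max(d) - min(d)) / s)
    }
    if (length(vals)) rs[k] <- mean(vals)
  }
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3L) return(1.0)
  dev <- log(rs[ok]) - log(vapply(sizes[ok], rs_expected, numeric(1)))
  slope <- stats::coef(stats::lm(dev ~ log(sizes[ok])))[[2L]]
  max(0, min(1.2, 0.5 + slope))
}

#' Drift-free cumulative integral via EMD and the Hurst exponent
#'
#' Integrates the series (cumulative trapezoid), decomposes the integral into
#' intrinsic mode functions, and reconstructs it from the components whose
#' Hurst exponent is at or below `hurst_cutoff`; components above the cutoff
#' (trends -- including the EMD residue) carry the integration drift and are
#' removed.  If the decomposition yields no usable components the function
#' falls back to polynomial (quadratic) detrending of the integral, with a
#' warning.
#'
#' @param x numeric series (e.g. vertical acceleration in m/s^2).
#' @param fs sampling rate, Hz.
#' @param hurst_cutoff drift threshold on the Hurst exponent (default 0.8).
#' @return list with `y` (drift-free integral), and `removed` (indices of the
#'   removed components; the residue is component `ncol(imf) + 1`).
#' @export
emd_drift_free_integral <- function(x, fs, hurst_cutoff = 0.8) {
  if (length(x) < 8L) stop("series too short to integrate", call. = FALSE)
  v <- cumtrapz_fs(x, fs)
  if (stats::sd(v) == 0) return(list(y = v - mean(v), removed = integer(0)))
  dec <- emd_decompose(v)
  comps <- cbind(dec$imf, dec$residue)
  if (ncol(dec$imf) == 0L) {
    warning("EMD produced no oscillatory component; polynomial detrend used")
    tt <- seq_along(v)
    fit <- stats::lm(v ~ tt + I(tt^2))
    return(list(y = stats::residuals(fit), removed = integer(0)))
  }
  H <- apply(comps, 2L, function(cc) {
    if (stats::sd(cc) == 0) return(1.0)
    hurst_exponent(cc)
  })
  removed <- which(H > hurst_cutoff)
  kept <- setdiff(seq_len(ncol(comps)), removed)
  y <- if (length(kept)) rowSums(comps[, kept, drop = FALSE]) else
    rep(0, length(v))
  list(y = y, removed = removed)
}
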