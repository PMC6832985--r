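# Agreement statistics between two measurement systems on paired values.

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d = x - y`: bias is `mean(d)`, the limits of agreement are
#' `bias +/- 1.96 * sd(d)`, and `loa_pct` expresses the LoA half-width as a
#' percentage of the grand mean of the pairwise means `(x + y) / 2`.
#'
#' @param x,y equal-length numeric vectors (length >= 3): the two systems'
#'   paired measurements.
#' @return named list `bias, loa_low, loa_high, loa_pct, n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  half <- 1.96 * stats::sd(d)
  list(bias = bias, loa_low = bias - half, loa_high = bias + half,
       loa_pct = half / mean((x + y) / 2) * 100, n = length(x))
}

#' Intraclass correlation (two-way random, absolute agreement, single
#' measure)
#'
#' ICC(2,1) from the two-way mean-squares decomposition of the paired table
#' (n subjects x 2 systems):
#' `(MSR - MSE) / (MSR + MSE + 2/n * (MSC - MSE))`.  Also returns the
#' conventional qualitative class: excellent (> 0.9), good (0.75-0.9),
#' moderate (0.5-0.75), poor (< 0.5).
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return named list `icc, class`; `icc` is `NA` when the table has zero
#'   total variance.
#' @export
icc_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  M <- cbind(x, y)
  if (stats::var(as.numeric(M)) == 0) {
    return(list(icc = NA_real_, class = NA_character_))
  }
  k <- 2L
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  cls <- if (icc > 0.9) "excellent" else if (icc >= 0.75) "good"
  else if (icc >= 0.5) "moderate" else "poor"
  list(icc = icc, class = cls)
}

#' Pearson correlation and root-mean-squared error
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return named list `r, rmse`; `r` is `NA` when either vector has zero
#'   variance.
#' @export
pearson_rmse <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y)
  list(r = r, rmse = sqrt(mean((x - y)^2)))
}

#' Full agreement report between two systems
#'
#' @param x,y equal-length numeric vectors: system under test and gold
#'   standard.
#' @return named list combining [bland_altman()], [icc_agreement()] and
#'   [pearson_rmse()].
#' @export
agreement_report <- function(x, y) {
  c(bland_altman(x, y), icc_agreement(x, y), pearson_rmse(x, y))
}
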