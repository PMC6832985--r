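# Drift-free integration, Hurst exponent, pendulum model and calibration.

fs <- 31.25

test_that("drift-free integration recovers closed-form integrals", {
  t <- tgrid(20, fs)
  # pure oscillation: integral is a sinusoid, no drift to remove
  y <- emd_drift_free_integral(cos(2 * pi * 2 * t), fs)$y
  expect_gt(stats::cor(y, sin(2 * pi * 2 * t) / (4 * pi)), 0.99)

  # added DC gives a linear drift in the integral; it must be removed
  y2 <- emd_drift_free_integral(cos(2 * pi * 2 * t) + 0.05, fs)$y
  expect_lt(abs(stats::coef(stats::lm(y2 ~ t))[[2L]]), 0.005)
  expect_gt(stats::cor(y2, sin(2 * pi * 2 * t) / (4 * pi)), 0.99)

  # zero in, zero out
  expect_equal(emd_drift_free_integral(rep(0, 500), fs)$y, rep(0, 500))
})

test_that("IMF pruning barely changes an already drift-free signal", {
  t <- tgrid(20, fs)
  x <- cos(2 * pi * 2 * t)
  y1 <- emd_drift_free_integral(x, fs)$y
  # prune the drift-free reconstruction again: decompose, drop trend-like
  # components, re-sum -- nothing should be left to remove
  dec <- emd_decompose(y1)
  comps <- cbind(dec$imf, dec$residue)
  keep <- apply(comps, 2L, function(cc) {
    stats::sd(cc) > 0 && hurst_exponent(cc) <= 0.8
  })
  y2 <- rowSums(comps[, keep, drop = FALSE])
  expect_lt(rms(y2 - y1) / rms(y1), 0.01)
})

test_that("Hurst exponent separates noise, trend and anti-persistence", {
  set.seed(42)
  expect_equal(hurst_exponent(stats::rnorm(4096)), 0.5, tolerance = 0.1)
  expect_gt(hurst_exponent(seq(0, 1, length.out = 512)), 0.9)
  expect_lt(hurst_exponent(rep(c(1, -1), 256)), 0.2)
  expect_equal(hurst_exponent(rep(3, 128)), 1.0)
  # independent cross-check against pracma on fresh white noise
  w <- stats::rnorm(4096)
  expect_equal(hurst_exponent(w),
               pracma::hurstexp(w, display = FALSE)$Hrs, tolerance = 0.12)
})

test_that("step height reads the programmed excursion", {
  f_step <- 1.8
  fs_fine <- 250   # dense sampling so the true extrema are on the grid
  t <- tgrid(10, fs_fine)
  disp <- 0.025 * sin(2 * pi * f_step * t)
  # one "step" per half displacement period: range is the full amplitude
  t_ic <- seq(0.25 / f_step, 9.5, by = 0.5 / f_step)
  ev <- new_gait_events(t_ic, t_ic + 0.1)
  h <- step_height(disp, ev, fs_fine)
  expect_equal(h, rep(0.05, length(h)), tolerance = 0.05 * 0.02)

  expect_equal(step_height(rep(0, length(t)), ev, fs_fine),
               rep(0, length(t_ic) - 1L))

  g <- gen_walk(f_step = 1.8, n_steps = 20L, h_amp = 0.03, seed = 2)
  sig <- preprocess_trial(g$recording, window = g$truth$window,
                          walking = TRUE)
  ev2 <- detect_contacts(sig$aV_f, fs, t0 = sig$t[1L])
  sl <- trial_step_lengths(sig$aV, ev2, fs, L = 1, K = 0, S = 0,
                           t0 = sig$t[1L])
  expect_gt(mean(sl$h, na.rm = TRUE), 0.025)
  expect_lt(mean(sl$h, na.rm = TRUE), 0.035)
})

test_that("pendulum step length matches its closed form", {
  expect_equal(pendulum_step_length(0.05, 1), 2 * sqrt(0.0975),
               tolerance = 1e-12)
  expect_equal(pendulum_step_length(0, 1), 0)
  expect_equal(pendulum_step_length(0.02, 1), 0.3979950, tolerance = 1e-6)
  expect_error(pendulum_step_length(1.2, 1), "pendulum")
  # strictly increasing in h on [0, L)
  h <- seq(0, 0.9, by = 0.01)
  expect_true(all(diff(pendulum_step_length(h, 1)) > 0))
})

test_that("K calibration is exact least squares", {
  S <- c(8, 9, 10, 11)
  L_hat <- c(0.6, 0.62, 0.64, 0.66)
  expect_equal(calibrate_K(L_hat + 1.13 * S, L_hat, S), 1.13,
               tolerance = 1e-10)
  expect_equal(calibrate_K(L_hat, L_hat, S), 0)
  expect_equal(calibrate_K(L_hat - 0.25 * S, L_hat, S), -0.25,
               tolerance = 1e-10)
  expect_error(calibrate_K(L_hat, L_hat, rep(0, 4)), "degenerate")
  expect_error(calibrate_K(L_hat, L_hat[1:3], S), "equal length")
})

test_that("corrected step length adds the shoe-size term", {
  expect_equal(corrected_step_length(0.05, 1, 0, 5)$length,
               2 * sqrt(0.0975), tolerance = 1e-12)
  out <- corrected_step_length(0.05, 1, 1.13, 0.09, t_step = 0.5)
  expect_equal(out$length, 2 * sqrt(0.0975) + 0.1017, tolerance = 1e-6)
  expect_equal(out$velocity, out$length / 0.5)
})

test_that("calibrated model recovers a programmed step length end to end", {
  K_true <- 1.13
  S <- 0.09
  L <- 1
  target <- 0.70
  pend <- target - K_true * S
  h_amp <- L - sqrt(L^2 - (pend / 2)^2)
  # calibration cohort: noisy synthetic trials, distinct seeds
  cal <- lapply(1:4, function(s) {
    g <- gen_walk(f_step = 1.8, n_steps = 20L, h_amp = h_amp, L = L,
                  seed = 100 + s)
    sig <- preprocess_trial(g$recording, window = g$truth$window,
                            walking = TRUE)
    ev <- detect_contacts(sig$aV_f, fs, t0 = sig$t[1L])
    sl <- trial_step_lengths(sig$aV, ev, fs, L = L, K = 0, S = 0,
                             t0 = sig$t[1L])
    ok <- !is.na(sl$length)
    list(hat = sl$length[ok], true = rep(target, sum(ok)))
  })
  K_fit <- calibrate_K(unlist(lapply(cal, `[[`, "true")),
                       unlist(lapply(cal, `[[`, "hat")),
                       rep(S, length(unlist(lapply(cal, `[[`, "hat")))))
  # held-out trial with the fitted K
  g <- gen_walk(f_step = 1.8, n_steps = 30L, h_amp = h_amp, L = L,
                seed = 999)
  sig <- preprocess_trial(g$recording, window = g$truth$window,
                          walking = TRUE)
  ev <- detect_contacts(sig$aV_f, fs, t0 = sig$t[1L])
  sl <- trial_step_lengths(sig$aV, ev, fs, L = L, K = K_fit, S = S,
                           t0 = sig$t[1L])
  expect_equal(mean(sl$length, na.rm = TRUE), target, tolerance = 0.10)
})
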