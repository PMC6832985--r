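# Contact detection, side assignment and temporal parameters.

fs <- 31.25
TOL2 <- 2 / fs   # two-sample tolerance

test_that("dominant frequency: single tone, noisy tone, two tones", {
  t <- tgrid(20, fs)
  expect_equal(dominant_frequency(sin(2 * pi * 1.8 * t), fs), 1.8,
               tolerance = 0.05)
  set.seed(4)
  noisy <- sin(2 * pi * 1.8 * t) +
    stats::rnorm(length(t), 0, sqrt(0.5 / 10^(10 / 10)))
  expect_equal(dominant_frequency(noisy, fs), 1.8, tolerance = 0.05)
  two <- sin(2 * pi * 1 * t) + 2 * sin(2 * pi * 2 * t)
  expect_equal(dominant_frequency(two, fs), 2, tolerance = 0.05)
  expect_error(dominant_frequency(sin(t[1:20]), fs), "at least 2 s")
})

test_that("synthetic gait at 1.9 Hz: every contact found, none invented", {
  g <- gen_walk(f_step = 1.9, n_steps = 20L, seed = 7)
  sig <- preprocess_trial(g$recording, window = g$truth$window,
                          walking = TRUE)
  ev <- detect_contacts(sig$aV_f, fs, t0 = sig$t[1L])
  ms <- match_stats(g$truth$t_ic, ev$t_ic, TOL2)
  expect_equal(unname(ms), c(1, 1))
  expect_equal(length(ev$t_ic), 20L)
  # ordered, admissible spacing
  expect_true(all(diff(ev$t_ic) >= 0.25 & diff(ev$t_ic) <= 2.25))
})

test_that("an injected spurious dip 0.1 s after a contact is pruned", {
  g <- gen_walk(f_step = 1.8, n_steps = 12L, seed = 5, noise_sd = 0)
  sig <- preprocess_trial(g$recording, window = g$truth$window,
                          walking = TRUE)
  av <- sig$aV_f
  # a deep gaus1-shaped dip shortly after the 5th contact
  tc <- g$truth$t_ic[5L] + 0.1
  s <- (sig$t - tc) / 0.05
  av2 <- av - 3 * exp(-s^2 / 2)
  ev <- detect_contacts(av2, fs, t0 = sig$t[1L])
  ms <- match_stats(g$truth$t_ic, ev$t_ic, TOL2)
  expect_equal(unname(ms[["recall"]]), 1)
  # nothing extra survives between the 5th and 6th true contact
  extra <- ev$t_ic[ev$t_ic > g$truth$t_ic[5L] + TOL2 &
                     ev$t_ic < g$truth$t_ic[6L] - TOL2]
  expect_length(extra, 0L)
})

test_that("degenerate inputs give empty events with a warning", {
  expect_warning(ev <- detect_contacts(rep(0, 200), fs), "flat|no")
  expect_length(ev$t_ic, 0L)
  expect_warning(ev2 <- detect_contacts(stats::rnorm(30), fs), "short")
  expect_length(ev2$t_ic, 0L)
})

test_that("event times shift with the input and ignore amplitude", {
  g <- gen_walk(f_step = 1.8, n_steps = 12L, seed = 9)
  sig <- preprocess_trial(g$recording, window = g$truth$window,
                          walking = TRUE)
  av <- sig$aV_f
  ev <- detect_contacts(av, fs, t0 = 0)
  # time shift by k samples; compare events in the interior of both windows
  # (the boundary guard may legitimately drop an event pushed to an edge)
  k <- 7L
  ev_sh <- detect_contacts(c(av[(k + 1):length(av)], rep(0, k)), fs,
                           t0 = 0)
  span <- c(0.3 + k / fs, (length(av) - k) / fs - 0.3)
  exp_t <- ev$t_ic[ev$t_ic > span[1L] & ev$t_ic < span[2L]] - k / fs
  got_t <- ev_sh$t_ic[ev_sh$t_ic > span[1L] - k / fs &
                        ev_sh$t_ic < span[2L] - k / fs]
  expect_equal(got_t, exp_t, tolerance = 1.01 / fs)
  # amplitude invariance (relative rules are scale-free)
  ev_sc <- detect_contacts(17.3 * av, fs, t0 = 0)
  expect_equal(ev_sc$t_ic, ev$t_ic)
  expect_equal(ev_sc$t_ec, ev$t_ec)
})

test_that("contact detection is exact across cadences and seeds", {
  for (f in c(1.4, 1.8, 2.2)) for (s in 1:4) {
    g <- gen_walk(f_step = f, n_steps = 20L, seed = s)
    sig <- preprocess_trial(g$recording, window = g$truth$window,
                            walking = TRUE)
    ev <- detect_contacts(sig$aV_f, fs, t0 = sig$t[1L])
    ms <- match_stats(g$truth$t_ic, ev$t_ic, TOL2)
    expect_equal(unname(ms), c(1, 1))
  }
})

test_that("side assignment: phase-locked yaw, zero yaw, sign flip", {
  g <- gen_walk(f_step = 1.8, n_steps = 20L, seed = 3)
  sig <- preprocess_trial(g$recording, window = g$truth$window,
                          walking = TRUE)
  ev <- detect_contacts(sig$aV_f, fs, t0 = sig$t[1L])
  ev <- assign_sides(ev, sig$yaw_f, fs, t0 = sig$t[1L])
  n <- length(ev$side)
  expect_true(all(ev$side[-1L] != ev$side[-n]))   # strict alternation
  expect_equal(ev$side[1L], "A")                  # phase-locked start

  # degenerate zero yaw: all A, then forced alternation from A
  ev0 <- assign_sides(ev, rep(0, nrow(sig)), fs, t0 = sig$t[1L])
  expect_equal(ev0$side, rep_len(c("A", "B"), n))

  # sign-flipped yaw swaps every label
  evf <- assign_sides(ev, -sig$yaw_f, fs, t0 = sig$t[1L])
  expect_true(all(evf$side != ev$side))
})

test_that("temporal parameters follow the event-time definitions", {
  ev <- new_gait_events(t_ic = c(0, 0.55, 1.10, 1.65),
                        t_ec = c(0.15, 0.70, 1.25, 1.80))
  tp <- temporal_params(ev)
  expect_equal(tp$t_stance[1L], 0.70)
  expect_equal(tp$t_stride[1L], 1.10)
  expect_equal(tp$t_step[1L], 0.55)
  expect_equal(tp$t_swing[1L], 0.40)
  expect_equal(tp$n_steps, 4L)

  # perfectly periodic events: step = p, stride = 2p, swing identity exact
  p <- 0.48
  evp <- new_gait_events(t_ic = p * (0:9), t_ec = p * (0:9) + 0.1)
  tpp <- temporal_params(evp)
  expect_equal(tpp$t_step, rep(p, 8L))
  expect_equal(tpp$t_stride, rep(2 * p, 8L))
  expect_equal(tpp$t_swing, tpp$t_stride - tpp$t_stance)

  # insufficient events: empty parameters, step count kept
  tp2 <- temporal_params(new_gait_events(c(0, 0.5), c(0.1)))
  expect_length(tp2$t_step, 0L)
  expect_equal(tp2$n_steps, 2L)
})

test_that("mean step time matches the generator to within one sample", {
  g <- gen_walk(f_step = 1.8, n_steps = 20L, seed = 13)
  sig <- preprocess_trial(g$recording, window = g$truth$window,
                          walking = TRUE)
  ev <- detect_contacts(sig$aV_f, fs, t0 = sig$t[1L])
  tp <- temporal_params(ev)
  expect_equal(mean(tp$t_step), 1 / 1.8, tolerance = 1 / fs)
  expect_equal(tp$n_steps, length(g$truth$t_ic))
})
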