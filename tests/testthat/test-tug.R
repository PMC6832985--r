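# Discrete wavelet approximation, TUG phase segmentation and features.

fs <- 31.25

test_that("db5 approximation keeps slow content and rejects fast", {
  t <- tgrid(12, fs)
  ramp <- t / 12
  a5 <- dwt_approximation(ramp, 5)
  expect_lt(rms(a5 - ramp) / rms(ramp), 0.02)

  s10 <- sin(2 * pi * 10 * t)
  expect_lt(rms(dwt_approximation(s10, 5)) / rms(s10), 0.10)

  expect_equal(dwt_approximation(rep(4.2, 400), 5), rep(4.2, 400),
               tolerance = 1e-9)
  expect_error(dwt_approximation(rep(1, 100), 5), "too short")
})

test_that("scripted TUG trials segment within a quarter second", {
  errs <- c()
  for (s in 1:5) {
    g <- gen_tug(seed = s)
    sig <- preprocess_trial(g$recording,
                            window = c(0, g$annotation$t_end),
                            walking = TRUE)
    ph <- detect_phases(sig$pitch, sig$yaw, fs, t0 = sig$t[1L])
    expect_equal(ph$phase, c("STS", "WALK1", "TURN1", "WALK2", "TURN2",
                             "StS"))
    # ordering invariant
    expect_true(!is.unsorted(ph$t_i[1:5]))
    expect_true(all(ph$t_i < ph$t_ii & ph$t_ii < ph$t_iii))
    tru <- g$truth$phases
    errs <- c(errs, unlist(ph[, c("t_i", "t_ii", "t_iii")]) -
                unlist(tru[, c("t_i", "t_ii", "t_iii")]))
  }
  expect_lt(max(abs(errs)), 0.25)
  expect_lt(sqrt(mean(errs^2)), 0.25)
})

test_that("turns are ordered by time, not amplitude", {
  g <- gen_tug(turn_peaks = c(80, 60), seed = 3)   # first turn is larger
  sig <- preprocess_trial(g$recording, window = c(0, g$annotation$t_end),
                          walking = TRUE)
  ph <- detect_phases(sig$pitch, sig$yaw, fs, t0 = sig$t[1L])
  t1 <- ph[ph$phase == "TURN1", ]; t2 <- ph[ph$phase == "TURN2", ]
  expect_lt(t1$t_ii, t2$t_ii)
  expect_equal(t1$t_ii, g$truth$phases$t_ii[3L], tolerance = 0.25)
})

test_that("pitch without a prominent extremum is a segmentation error", {
  set.seed(1)
  n <- 700
  pitch <- stats::rnorm(n, 0, 0.5)
  yaw <- 60 * exp(-((seq_len(n) / fs - 8)^2) / 0.4) +
    70 * exp(-((seq_len(n) / fs - 14)^2) / 0.4)
  expect_error(detect_phases(pitch, yaw, fs), "below")
})

test_that("stage statistics follow piecewise-linear closed forms", {
  # triangular pitch burst: 0 -> 50 deg/s over 0.5 s -> 0 over 0.5 s
  dur <- 20
  t <- tgrid(dur, fs)
  pitch <- numeric(length(t))
  b <- t >= 2 & t <= 3
  pitch[b] <- 50 * (1 - abs(t[b] - 2.5) / 0.5)
  sig <- data.frame(t = t, aAP = rep(0, length(t)), aML = 0, aV = 0,
                    pitch = pitch, yaw = 0)
  attr(sig, "fs") <- fs
  class(sig) <- c("aligned_signal", "data.frame")
  phases <- data.frame(
    phase = c("STS", "WALK1", "TURN1", "WALK2", "TURN2", "StS"),
    t_i = c(2, 3.5, 6, 9, 12, 15),
    t_ii = c(2.5, 4, 6.5, 9.5, 12.5, 15.5),
    t_iii = c(3, 5.5, 8, 11, 14, 16.5))
  ev <- new_gait_events(c(4, 4.5, 5, 9.5, 10, 10.5),
                        c(4.1, 4.6, 5.1, 9.6, 10.1, 10.6))
  tf <- tug_features(sig, phases, ev)
  expect_length(tf, 43L)
  expect_equal(tf[["STS: Range Pitch Vel (i-ii)"]], 50, tolerance = 0.5)
  expect_equal(tf[["STS: Mean Pitch Acc (i-ii)"]], 100, tolerance = 1)
  expect_equal(tf[["STS: Mean Pitch Acc (ii-iii)"]], -100, tolerance = 1)
  expect_equal(tf[["STS: Duration (i-iii)"]], 1)
  # zero AP acceleration during the sit phases
  expect_equal(tf[["StS: Mean Acc AP (i-iii)"]], 0)
  expect_equal(tf[["StS: SD Acc AP (i-iii)"]], 0)
  expect_equal(tf[["StS: Median Acc AP (i-iii)"]], 0)
  # scripted walk events: 3 + 3 contacts inside the walk windows
  expect_equal(tf[["WALK: N Steps"]], 6)
  expect_equal(tf[["WALK: Mean Step Time"]], 0.5)
})

test_that("turn features ignore the sign of yaw", {
  g <- gen_tug(seed = 4)
  sig <- preprocess_trial(g$recording, window = c(0, g$annotation$t_end),
                          walking = TRUE)
  ph <- detect_phases(sig$pitch, sig$yaw, fs, t0 = sig$t[1L])
  ev <- tug_gait_events(sig, ph)
  tf <- tug_features(sig, ph, ev)
  sig2 <- sig
  sig2$yaw <- -sig2$yaw
  ph2 <- detect_phases(sig2$pitch, sig2$yaw, fs, t0 = sig2$t[1L])
  tf2 <- tug_features(sig2, ph2, ev)
  for (nm in c("TURN1: Max Yaw Vel", "TURN2: Max Yaw Vel",
               "TURN1: Mean Yaw Acc (i-ii)", "TURN2: Mean Yaw Acc (ii-iii)",
               "TURN1: Duration", "TURN2: Duration")) {
    expect_equal(tf2[[nm]], tf[[nm]], tolerance = 1e-6)
  }
})

test_that("scripted walk step counts are recovered exactly", {
  for (s in 1:4) {
    g <- gen_tug(steps_per_walk = 4L, seed = s)
    sig <- preprocess_trial(g$recording, window = c(0, g$annotation$t_end),
                            walking = TRUE)
    ph <- detect_phases(sig$pitch, sig$yaw, fs, t0 = sig$t[1L])
    ev <- tug_gait_events(sig, ph)
    tf <- tug_features(sig, ph, ev)
    expect_equal(tf[["WALK: N Steps"]], 8)
    expect_equal(tf[["TURN1: N Steps"]], 0)
  }
})

test_that("phase durations stay inside the annotated trial", {
  g <- gen_tug(seed = 6)
  sig <- preprocess_trial(g$recording, window = c(0, g$annotation$t_end),
                          walking = TRUE)
  ph <- detect_phases(sig$pitch, sig$yaw, fs, t0 = sig$t[1L])
  dur5 <- sum((ph$t_iii - ph$t_i)[ph$phase != "WALK1" & ph$phase != "WALK2"]) +
    sum((ph$t_iii - ph$t_i)[ph$phase %in% c("WALK1", "WALK2")])
  expect_lte(dur5, g$annotation$t_end - g$annotation$t_start)
})
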