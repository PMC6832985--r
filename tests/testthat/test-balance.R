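# Postural sway features: spectral, time-domain and ellipse.

fs <- 31.25

test_that("spectral features on line spectra and white noise", {
  t <- tgrid(60, fs)
  sp <- spectral_features(sin(2 * pi * 1 * t), fs)
  df <- fs / length(t)
  expect_equal(unname(sp), rep(1, 3), tolerance = 2 * df)
  expect_lte(sp[["F50"]], sp[["F95"]])

  two <- sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t)
  sp2 <- spectral_features(two, fs)
  expect_equal(sp2[["SC"]], 2, tolerance = 2 * df)
  expect_equal(sp2[["F50"]], 1, tolerance = 2 * df)

  set.seed(8)
  sp3 <- spectral_features(stats::rnorm(8192), fs)
  expect_equal(sp3[["F50"]], fs / 4, tolerance = 0.5)

  expect_true(all(is.na(spectral_features(rep(0, 400), fs))))
})

test_that("time-domain features match sinusoid closed forms and scale", {
  A <- 0.7; f <- 1.2
  t <- tgrid(40, fs)
  x <- A * sin(2 * pi * f * t)
  tf <- time_features(x, fs)
  expect_equal(tf[["RMS"]], A / sqrt(2), tolerance = 0.02 * A)
  expect_equal(tf[["MaxAcc"]], A, tolerance = 0.02 * A)
  expect_equal(tf[["MeanAcc"]], 2 * A / pi, tolerance = 0.02 * A)
  expect_equal(tf[["Jerk"]], 2 * pi * f * A / sqrt(2),
               tolerance = 0.04 * 2 * pi * f * A)

  expect_equal(unname(time_features(rep(0, 400), fs)), rep(0, 6))

  # homogeneity of degree 1 (sway velocity via EMD within 1%)
  c0 <- 3.7
  tf_sc <- time_features(c0 * x, fs)
  for (nm in c("MaxAcc", "MeanAcc", "RMS", "Jerk", "SPathA")) {
    expect_equal(tf_sc[[nm]], c0 * tf[[nm]], tolerance = 1e-9)
  }
  expect_equal(tf_sc[["SwayV"]], c0 * tf[["SwayV"]],
               tolerance = 0.01 * c0 * tf[["SwayV"]])
})

test_that("the 95% ellipse has chi-square area and coverage", {
  set.seed(9)
  n <- 1e5
  X <- matrix(stats::rnorm(2 * n, 0, 0.1), ncol = 2)
  el <- ellipse_features(X[, 1L], X[, 2L])
  expect_equal(el[["EllipseArea"]], pi * stats::qchisq(0.95, 2) * 0.01,
               tolerance = 0.03 * pi * stats::qchisq(0.95, 2) * 0.01)
  md <- stats::mahalanobis(X, colMeans(X), stats::cov(X))
  cover <- mean(md <= stats::qchisq(0.95, 2))
  expect_equal(cover, 0.95, tolerance = 0.01)

  # collinear data: degenerate ellipse
  z <- stats::rnorm(100)
  expect_warning(el0 <- ellipse_features(z, 2 * z), "rank-deficient")
  expect_equal(el0[["EllipseArea"]], 0, tolerance = 1e-20)

  # axis-aligned anisotropy: angle near 0, axis ratio near 2
  set.seed(10)
  ap <- stats::rnorm(5e4, 0, 0.2); ml <- stats::rnorm(5e4, 0, 0.1)
  el2 <- ellipse_features(ap, ml)
  expect_lt(abs(el2[["EllipseAngle_AP"]]), 3)
  expect_equal(el2[["EllipseAxis_AP"]] / el2[["EllipseAxis_ML"]], 2,
               tolerance = 0.1)
})

test_that("rotating the sway plane preserves area and shifts the angle", {
  set.seed(12)
  ap <- stats::rnorm(2e4, 0, 0.25); ml <- stats::rnorm(2e4, 0, 0.08)
  base <- ellipse_features(ap, ml)
  phi <- 25
  cr <- cos(deg2rad(phi)); sr <- sin(deg2rad(phi))
  ap2 <- cr * ap - sr * ml; ml2 <- sr * ap + cr * ml
  rot <- ellipse_features(ap2, ml2)
  expect_equal(rot[["EllipseArea"]], base[["EllipseArea"]],
               tolerance = 0.02 * base[["EllipseArea"]])
  d_ang <- (rot[["EllipseAngle_AP"]] - base[["EllipseAngle_AP"]] - phi) %% 180
  expect_true(min(d_ang, 180 - d_ang) < 3)
})

test_that("each condition yields the full named 23-feature set", {
  g <- gen_sway(cov = diag(c(0.03, 0.02)^2), duration = 30, seed = 5)
  sig <- preprocess_trial(g$recording,
                          window = c(g$annotation$t_start,
                                     g$annotation$t_end))
  feats <- bbs_condition_features(sig, "SU")
  expect_length(feats, 23L)
  expect_named(feats, bbs_feature_names())
  expect_false(anyNA(feats))
  expect_lte(feats[["F50% AP"]], feats[["F95% AP"]])
  expect_lte(feats[["Mean Acc AP"]], feats[["Max Acc AP"]])
  # RMS equals the driven covariance diagonal
  expect_equal(feats[["RMS AP"]], 0.03, tolerance = 0.002)
  expect_equal(feats[["RMS ML"]], 0.02, tolerance = 0.002)

  # identical signals give identical features; zero windows keep shape
  expect_identical(feats, bbs_condition_features(sig, "SOL"))
  zero <- sig
  zero$aAP <- zero$aML <- rep(0, nrow(zero))
  zf <- suppressWarnings(bbs_condition_features(zero, "SU"))
  expect_length(zf, 23L)
  expect_true(all(is.na(zf[c("F50% AP", "F95% AP", "SC AP")])))
  expect_equal(unname(zf["RMS AP"]), 0)
})

test_that("narrow-band sway lands F50 inside the programmed band", {
  g <- gen_sway(cov = diag(c(0.03, 0.03)^2), band = c(0.9, 1.1),
                duration = 60, seed = 6)
  sig <- preprocess_trial(g$recording,
                          window = c(g$annotation$t_start,
                                     g$annotation$t_end))
  sp <- spectral_features(sig$aAP, fs)
  expect_gte(sp[["F50"]], 0.85)
  expect_lte(sp[["F50"]], 1.15)
})
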