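test_that("QYes counts yes answers within its bounds", {
  expect_equal(qyes(questionnaire_response(rep(1, 30))), 30)
  expect_equal(qyes(questionnaire_response(rep(0, 30))), 0)
  expect_equal(qyes(questionnaire_response(rep(c(1, 0), c(7, 23)))), 7)
})

test_that("velocity series implements the discrete differentiation", {
  rec <- drawing_recording("v", "right", 1, data.frame(
    t = c(0, 1), x = c(0, 3), y = c(0, 4), force = 1))
  v <- velocity_series(rec)
  expect_equal(v$v, c(0, 5))  # 3-4-5 triangle; first element defined 0

  dup_move <- drawing_recording("v", "right", 1, data.frame(
    t = c(0, 1, 1), x = c(0, 1, 2), y = c(0, 0, 0), force = 1))
  expect_error(velocity_series(dup_move), "repeated timestamp")
  dup_still <- drawing_recording("v", "right", 1, data.frame(
    t = c(0, 1, 1, 2), x = c(0, 1, 1, 2), y = 0, force = 1))
  expect_warning(v2 <- velocity_series(dup_still), "duplicate")
  expect_equal(v2$v, c(0, 1, 1))
})

test_that("constant-speed sampling of the template yields near-zero velocity SD", {
  # arc-length parametrization: equal arc steps at uniform time steps
  theta_dense <- seq(0.2, 8 * pi, length.out = 60000)
  pts <- spiral_points(tpl, theta_dense)
  arc <- c(0, cumsum(sqrt(diff(pts$x)^2 + diff(pts$y)^2)))
  s_eq <- seq(0, max(arc), length.out = 2000)
  theta_eq <- approx(arc, theta_dense, xout = s_eq)$y
  pts_eq <- spiral_points(tpl, theta_eq)
  rec <- drawing_recording("const", "right", 1, data.frame(
    t = seq(0, 20, length.out = 2000), x = pts_eq$x, y = pts_eq$y,
    force = 1))
  v <- velocity_series(rec)$v[-1]  # drop the defined leading zero
  expect_lt(sd(v) / mean(v), 1e-3)
})

test_that("velocity and its population variance match brute-force oracles", {
  withr::local_seed(21)
  for (i in 1:50) {
    rec <- random_recording(n = sample(50:150, 1))
    s <- rec$samples
    n <- nrow(s)
    oracle_v <- numeric(n)
    for (j in 2:n) {
      oracle_v[j] <- sqrt((s$x[j] - s$x[j - 1])^2 +
                            (s$y[j] - s$y[j - 1])^2) /
        (s$t[j] - s$t[j - 1])
    }
    v <- velocity_series(rec)$v
    expect_equal(v, oracle_v, tolerance = 1e-12)

    mu <- mean(oracle_v)
    eq2 <- sum((oracle_v - mu)^2) / n
    expect_equal(spiraldx:::pop_sd(v)^2, eq2, tolerance = 1e-12)
  }
})

test_that("spectral laterality feature matches a brute-force DFT oracle", {
  n <- 1200
  t <- (0:(n - 1)) / 240
  mk <- function(d) structure(data.frame(t = t, d = d),
                              class = c("distance_series", "data.frame"))
  sine <- mk(0.3 * sin(2 * pi * 5 * t))
  flat <- mk(rep(0, n))

  # identical sides cancel exactly
  expect_equal(f1c_distance_fft(sine, sine), 0)

  # oracle: direct DFT at matching resolution, same band/binning rules
  k <- 0:floor(n / 2)
  W <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  mag <- abs(as.vector(W %*% sine$d)) / n
  freq <- k * 240 / n
  edges <- seq(3, 15, length.out = 21)
  inband <- freq >= 3 & freq <= 15
  bin <- cut(freq[inband], edges, include.lowest = TRUE, labels = FALSE)
  bins <- vapply(1:20, function(b) {
    m <- mag[inband][bin == b]
    if (length(m) == 0) 0 else mean(m)
  }, numeric(1))
  oracle_std <- sqrt(mean((bins - mean(bins))^2))
  expect_equal(f1c_distance_fft(sine, flat), oracle_std, tolerance = 1e-9)

  # the 5 Hz component dominates its bin
  prof <- spiraldx:::fft_bin_profile(sine)
  peak <- prof$bin_centers[which.max(prof$bins)]
  expect_lt(abs(peak - 5), 0.6)
})

test_that("white-noise distance series on both sides gives a small laterality value", {
  withr::local_seed(33)
  n <- 4800
  t <- (0:(n - 1)) / 240
  mk <- function(d) structure(data.frame(t = t, d = d),
                              class = c("distance_series", "data.frame"))
  vals <- replicate(10, f1c_distance_fft(mk(rnorm(n, 0, 0.1)),
                                         mk(rnorm(n, 0, 0.1))))
  ref <- spiraldx:::fft_bin_profile(mk(0.3 * sin(2 * pi * 5 * t)))$bin_std
  expect_lt(mean(vals), 0.2 * ref)
})

test_that("precision features match their defining formulas", {
  expect_equal(precision_features(rep(0, 10)),
               c(F2 = 0, F3 = 0, F4 = 0))
  expect_equal(precision_features(c(0.5, -0.5)),
               c(F2 = 0.5, F3 = 0.5, F4 = 0.5))
  withr::local_seed(3)
  d <- rnorm(500)
  p <- precision_features(d)
  expect_equal(p[["F2"]], max(abs(d)))
  expect_equal(p[["F3"]], mean(abs(d)))
  expect_equal(p[["F4"]], sqrt(mean((d - mean(d))^2)))
})

test_that("direction-change counts follow the sign-change definition", {
  mk_radial <- function(r) drawing_recording("d", "right", 1, data.frame(
    t = seq_along(r), x = r, y = 0, force = 1))
  expect_equal(direction_change_features(mk_radial(1:20))[["F5"]], 0)
  expect_equal(direction_change_features(mk_radial(c(0.01, 1, 0.5, 1.5, 1)))[["F5"]], 3)

  # sinusoid over k full periods: F6 ~ 2k extrema, against a brute-force
  # extrema counter
  withr::local_seed(5)
  for (k in c(3, 7)) {
    t <- seq(0, k, length.out = 1500)
    x <- sin(2 * pi * t) + 3
    rec <- drawing_recording("s", "right", 1,
                             data.frame(t = t, x = x, y = t + 1, force = 1))
    extrema <- sum(diff(sign(diff(x))) != 0)
    f6 <- direction_change_features(rec)[["F6"]]
    expect_equal(f6, extrema)
    expect_lte(abs(f6 - 2 * k), 1)
  }
})

test_that("force features are mean, population SD and median", {
  mk <- function(force) drawing_recording("f", "left", 1, data.frame(
    t = seq_along(force), x = seq_along(force), y = 0, force = force))
  expect_equal(force_features(mk(rep(1, 5))), c(F8 = 1, F9 = 0, F10 = 1))
  expect_equal(force_features(mk(c(0, 2))), c(F8 = 1, F9 = 1, F10 = 1))
  withr::local_seed(8)
  f <- abs(rnorm(200))
  got <- force_features(mk(f))
  expect_equal(got[["F8"]], mean(f))
  expect_equal(got[["F9"]], sqrt(mean((f - mean(f))^2)))
  expect_equal(got[["F10"]], median(f))
})

test_that("time and velocity features compose clipping and Eq.-2 variance", {
  rec <- ideal_recording(n = 1000, duration = 30)
  tv <- time_velocity_features(rec)
  expect_equal(tv[["F11"]], 30)

  withr::local_seed(9)
  rec2 <- random_recording(n = 200)
  tv2 <- time_velocity_features(rec2)
  clipped <- clip_time_series(rec2$samples)
  v <- velocity_series(drawing_recording("r", "left", 1, clipped))$v
  expect_equal(tv2[["F12"]], mean(v), tolerance = 1e-12)
  expect_equal(tv2[["F13"]]^2, sum((v - mean(v))^2) / length(v),
               tolerance = 1e-12)
})

test_that("log transform is the epsilon-shifted natural log and monotone", {
  expect_equal(log_transform_features(exp(1) - 1e-9), 1)
  expect_equal(log_transform_features(0), log(1e-9))
  expect_error(log_transform_features(-0.1), "domain error")
  withr::local_seed(10)
  x <- sort(runif(50, 0, 5))
  expect_true(all(diff(log_transform_features(x)) >= 0))
})

test_that("an ideal drawer yields the fixed-point feature vector", {
  p <- ideal_participant("ID1")
  fv <- extract_feature_vector(p)
  expect_equal(fv$QYes, 0L)
  expect_lt(fv$F2_MaxDistance, 1e-9)
  expect_lt(fv$F3_MeanDistance, 1e-9)
  expect_lt(fv$F4_StdDevDistance, 1e-9)
  expect_equal(fv$F1c_DistanceFFT, 0)  # identical sides
  expect_lt(fv$F13_StdDevVelocity, 0.05 * fv$F12_MeanVelocity)
  expect_equal(fv$F5_ChangeOfRadiusDirection, 0)
})

test_that("injected tremor frequencies land in the right spectral bin", {
  for (f in c(4, 5, 6, 8, 10)) {
    rec <- tremor_recording(0.3, f, n = 7200, duration = 30)
    d <- signed_distance_series(rec, tpl)
    dc <- structure(clip_time_series(as.data.frame(d)),
                    class = c("distance_series", "data.frame"))
    prof <- spiraldx:::fft_bin_profile(dc)
    peak <- prof$bin_centers[which.max(prof$bins)]
    expect_lt(abs(peak - f), 0.6)
  }
})

test_that("doubling tremor amplitude doubles the distance features", {
  r1 <- tremor_recording(0.2, 5, n = 6000)
  r2 <- tremor_recording(0.4, 5, n = 6000)
  p1 <- precision_features(remove_top_values(
    signed_distance_series(r1, tpl)$d))
  p2 <- precision_features(remove_top_values(
    signed_distance_series(r2, tpl)$d))
  for (k in c("F2", "F3", "F4")) {
    expect_equal(p2[[k]] / p1[[k]], 2, tolerance = 0.02)
  }
})

test_that("PD phenotype scores above CG on distance features in paired simulations", {
  withr::local_seed(271)
  cc <- cohort_config()
  phs <- phenotype_presets()
  template <- make_reference_spiral()
  n_pairs <- 20L
  wins <- 0L
  for (i in seq_len(n_pairs)) {
    traits_pd <- list(tremor_freq = 5, tremor_amplitude = 0.3,
                      affected = "left", duration = 20, force_mean = 1.05)
    both_hands <- function(ph, traits, id) {
      recs <- list()
      for (h in c("left", "right")) {
        for (r in 1:2) {  # the protocol's two repetitions per hand
          recs[[length(recs) + 1L]] <-
            simulate_drawing(ph, cc, h, r, traits, id)
        }
      }
      recs
    }
    traits_cg <- spiraldx:::sample_participant_traits(phs$CG)
    p_pd <- participant_record(
      "pd", "PD", 65, "male",
      recordings = both_hands(phs$PD, traits_pd, "pd"),
      questionnaire = simulate_questionnaire(phs$PD))
    p_cg <- participant_record(
      "cg", "CG", 60, "male",
      recordings = both_hands(phs$CG, traits_cg, "cg"),
      questionnaire = simulate_questionnaire(phs$CG))
    fv_pd <- extract_feature_vector(p_pd, template)
    fv_cg <- extract_feature_vector(p_cg, template)
    wins <- wins + all(fv_pd$F2_MaxDistance > fv_cg$F2_MaxDistance,
                       fv_pd$F3_MeanDistance > fv_cg$F3_MeanDistance,
                       fv_pd$F4_StdDevDistance > fv_cg$F4_StdDevDistance,
                       fv_pd$F1c_DistanceFFT > fv_cg$F1c_DistanceFFT)
  }
  expect_gte(wins / n_pairs, 0.95)
})
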