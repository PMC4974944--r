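test_that("detection requires distance, sector and signal-facing conditions", {
  s <- sensor_spec(pi, 1)
  g <- signal_spec(pi)
  # head-on on the sensor axis: both angular offsets are zero
  expect_true(is_detected(0.5, 0, heading = pi, sensor = s, signal = g))
  # outside the detection distance, everything else ideal
  expect_false(is_detected(1.5, 0, heading = pi, sensor = s, signal = g))
  # omnidirectional sensor and signal capture any position within r
  gas_s <- sensor_spec(2 * pi, 1)
  gas_g <- signal_spec(2 * pi)
  set.seed(42)
  ang <- runif(50, 0, 2 * pi)
  rad <- sqrt(runif(50))
  expect_true(all(is_detected(rad * cos(ang), rad * sin(ang),
                              runif(50, 0, 2 * pi), gas_s, gas_g)))
  # inside the sector but facing directly away: signal cone misses the sensor
  expect_false(is_detected(0.5, 0, heading = 0, sensor = s,
                           signal = signal_spec(pi / 2)))
  # angle comparisons wrap modulo 2*pi
  expect_true(is_detected(0.5, 0, heading = pi + 6 * pi, sensor = s, signal = g))
})

test_that("profile width matches the known special cases", {
  gammas <- seq(0, 2 * pi, length.out = 37)
  # gas model: constant chord 2r
  expect_equal(
    profile_width(gammas, sensor_spec(2 * pi, 2), signal_spec(2 * pi)),
    rep(4, 37)
  )
  # a silent animal is never detected
  expect_equal(
    profile_width(gammas, sensor_spec(pi, 1), signal_spec(0)),
    rep(0, 37)
  )
  # SE2 geometry, head-on approach: profile limited by the signal width
  th <- 15 * pi / 8; al <- pi / 2
  expect_equal(
    profile_width(pi, sensor_spec(th, 1), signal_spec(al)),
    2 * sin(al / 2),
    tolerance = 1e-12
  )
  # widths always within [0, 2r]
  p <- profile_width(seq(0, 2 * pi, length.out = 720),
                     sensor_spec(4.2, 1.3), signal_spec(2.1))
  expect_true(all(p >= 0 & p <= 2 * 1.3))
})

test_that("profile width agrees with brute-force line sampling", {
  set.seed(7)
  for (k in 1:5) {
    th <- runif(1, 0.3, 2 * pi)
    al <- runif(1, 0.3, 2 * pi)
    gm <- runif(1, 0, 2 * pi)
    s <- sensor_spec(th, 1)
    g <- signal_spec(al)
    expect_equal(
      profile_width(gm, s, g),
      grem:::profile_width_sampled(gm, s, g, n_offsets = 8001, n_along = 801),
      tolerance = 5e-3
    )
  }
})

test_that("numeric mean profile reproduces gas, wide-sensor and SE2 values", {
  expect_equal(pbar_numeric(2 * pi, 2 * pi), 2, tolerance = 1e-6)
  expect_equal(pbar_numeric(2 * pi, pi), 2, tolerance = 1e-6)
  # worked SE2 submodel value at theta = 15*pi/8, alpha = pi/2
  expect_equal(pbar_numeric(15 * pi / 8, pi / 2), 1.3948261245267015,
               tolerance = 1e-5)
  pr <- mean_profile_numeric(sensor_spec(pi, 1), signal_spec(pi / 3))
  expect_s3_class(pr, "grem_profile")
  expect_identical(pr$method, "numeric")
})

test_that("closed-form mean profile matches its anchors", {
  expect_identical(pbar_closed(2 * pi, 2 * pi), 2)
  # SE2 expression evaluated directly
  th <- 15 * pi / 8; al <- pi / 2
  expect_equal(pbar_closed(th, al),
               (th * sin(al / 2) - cos(al / 2) + cos(al / 2 + th)) / pi)
  expect_equal(pbar_closed(th, al), 1.3948261245267015, tolerance = 1e-12)
  # classic camera-trap REM: r * (2 + theta) / pi for narrow sensors
  expect_equal(pbar_closed(pi / 4, 2 * pi), (2 + pi / 4) / pi)
  expect_equal(pbar_closed(pi / 4, 2 * pi), pbar_numeric(pi / 4, 2 * pi),
               tolerance = 1e-4)
  # degenerate widths give exactly zero
  expect_identical(pbar_closed(2 * pi, 0), 0)
  expect_error(mean_profile_closed(sensor_spec(7, 1), signal_spec(pi)),
               "theta")
})

test_that("closed form equals the numerical oracle across parameter space", {
  # jittered grid so no point sits exactly on a region boundary
  set.seed(11)
  th <- sort(runif(21, 0.05, 2 * pi))
  al <- sort(runif(21, 0.05, 2 * pi))
  for (t in th) {
    cf <- vapply(al, function(a) pbar_closed(t, a), numeric(1))
    nu <- vapply(al, function(a) pbar_numeric(t, a), numeric(1))
    expect_true(all(abs(cf - nu) <= 5e-3))
  }
})

test_that("mean profile is bounded, vanishes at alpha = 0 and is monotone", {
  th <- seq(2 * pi / 25, 2 * pi, length.out = 25)
  al <- seq(2 * pi / 25, 2 * pi, length.out = 25)
  pb <- outer(th, al, function(t, a) grem:::pbar_closed_num(t, a, 1))
  expect_true(all(pb >= 0 & pb <= 2))
  expect_true(all(vapply(th, function(t) pbar_closed(t, 0), numeric(1)) == 0))
  # widening the sensor or the signal cannot lose detections
  expect_true(all(diff(pb) >= -1e-12))        # in theta, fixed alpha
  expect_true(all(t(diff(t(pb))) >= -1e-12))  # in alpha, fixed theta
})

test_that("adjacent closed forms agree on their shared boundaries", {
  eps <- 1e-9
  al_small <- seq(0.2, pi - 0.05, length.out = 25)
  # SW | SE2 along theta = 2*pi - alpha/2 (alpha < pi)
  expect_true(all(abs(
    grem:::pbar_sw(2 * pi - al_small / 2, al_small, 1) -
      grem:::pbar_se2(2 * pi - al_small / 2, al_small, 1)) <= eps))
  al_big <- seq(pi + 0.05, 2 * pi, length.out = 25)
  # NW | NE1 along theta = 2*pi - alpha/2 (alpha > pi)
  expect_true(all(abs(
    grem:::pbar_nw(2 * pi - al_big / 2, al_big, 1) -
      grem:::pbar_ne1(2 * pi - al_big / 2, al_big, 1)) <= eps))
  # NE1 | NE2 along theta + alpha = 3*pi
  expect_true(all(abs(
    grem:::pbar_ne1(3 * pi - al_big, al_big, 1) -
      grem:::pbar_ne2(3 * pi - al_big, al_big, 1)) <= eps))
  th_any <- seq(0.2, 2 * pi, length.out = 25)
  # SW | NW and SE2 | NE1 along alpha = pi
  expect_true(all(abs(grem:::pbar_sw(th_any, pi, 1) -
                        grem:::pbar_nw(th_any, pi, 1)) <= eps))
  expect_true(all(abs(grem:::pbar_se2(th_any, pi, 1) -
                        grem:::pbar_ne1(th_any, pi, 1)) <= eps))
})

test_that("submodels are classified by parameter region", {
  r1 <- sensor_spec(2 * pi, 1)
  expect_identical(classify_submodel(r1, signal_spec(2 * pi)), "gas")
  expect_identical(classify_submodel(sensor_spec(pi / 4, 1), signal_spec(2 * pi)),
                   "REM")
  expect_identical(classify_submodel(sensor_spec(15 * pi / 8, 1),
                                     signal_spec(pi / 2)), "SE2")
  expect_identical(classify_submodel(sensor_spec(pi / 2, 1), signal_spec(pi / 2)),
                   "SW")
  expect_identical(classify_submodel(sensor_spec(pi / 2, 1),
                                     signal_spec(3 * pi / 2)), "NW")
  expect_identical(classify_submodel(sensor_spec(15 * pi / 8, 1),
                                     signal_spec(3 * pi / 2)), "NE2")
  expect_identical(classify_submodel(sensor_spec(2 * pi, 1), signal_spec(0)),
                   "degenerate")
  expect_error(signal_spec(-1), "alpha")
  expect_error(sensor_spec(0, 1), "theta")
})
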