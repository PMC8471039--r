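test_that("characteristic speed and optimal distance behave as derived", {
  expect_equal(characteristic_speed(0, 2, 1), 2)
  expect_equal(characteristic_speed(1, 2, 1), 0)
  expect_equal(characteristic_speed(2, 1, 1), -exp(-2))
  expect_equal(optimal_distance(1), 2)
  expect_equal(optimal_distance(2), optimal_distance(1) / 2)
  # numeric maximisation of |V0| over the outer region matches 2/k
  for (k in c(0.5, 1, 3)) {
    zopt <- stats::optimize(function(z) -abs(characteristic_speed(z, 1, k)),
                            c(1 / k + 1e-9, 10 / k), tol = 1e-10)$minimum
    expect_equal(zopt, 2 / k, tolerance = 1e-6)
  }
  # |V0| is unimodal beyond 1/k: increasing to 2/k then decreasing
  zz <- seq(1.05, 8, length.out = 300)
  vv <- abs(characteristic_speed(zz, 1, 1))
  ipk <- which.max(vv)
  expect_true(all(diff(vv[1:ipk]) > 0))
  expect_true(all(diff(vv[ipk:length(vv)]) < 0))
})

test_that("flow gain solves the cell-crossing self-consistency relation", {
  p <- model_params(omega = 4, u_max = 5)
  # vanishes with the flow
  expect_equal(flow_gain(1, -pi / 2, p), 0)
  # high-frequency limit: 2 V0 / pi
  phf <- model_params(omega = 4e6, u_max = 5)
  V0 <- abs(characteristic_speed(2, 5, 1))
  expect_equal(flow_gain(2, -pi / 2, phf), 2 * V0 / pi, tolerance = 1e-5)
  # first-order fixed point: re-substituting the gain changes it only at
  # second order in V0/omega
  vf <- flow_gain(2, -pi / 2, p)
  vf2 <- (2 * V0 / pi) * (1 - (1 / 4) * (-1 + vf))
  expect_lt(abs(vf2 - vf), 4 * (2 * V0 / pi) * (V0 / 4)^2)
  # frozen-state simulation oracle agrees to within the first-order error
  z0 <- distance_for_speed(0.62, 5, 1)
  orc <- frozen_transport_oracle(z0, p)
  expect_equal(flow_gain(z0, -pi / 2, p), orc$v_flow, tolerance = 0.12)
})

test_that("switch period matches the frozen-state oracle and is affine in omega", {
  z0 <- distance_for_speed(0.62, 5, 1)
  for (om in c(4, 8)) {
    p <- model_params(omega = om, u_max = 5)
    orc <- frozen_transport_oracle(z0, p, T = 25)
    expect_equal(switch_time(z0, -pi / 2, p), orc$T_switch, tolerance = 0.03)
  }
  # 1/T_switch is affine in omega with slope 1/pi at fixed V0, theta0
  vf <- 0.37  # hold the gain fixed to isolate the affine structure
  inv <- vapply(c(4, 6, 8, 12), function(om) {
    1 / switch_time(z0, -pi / 2, model_params(omega = om, u_max = 5),
                    v_flow = vf)
  }, numeric(1))
  slopes <- diff(inv) / diff(c(4, 6, 8, 12))
  expect_equal(slopes, rep(1 / pi, 3), tolerance = 1e-12)
  # monotone: higher frequency, faster switching
  expect_true(all(diff(inv) > 0))
  # wave slower than the swimmer: no synchronised regime
  suppressWarnings(
    expect_error(switch_time(2, -pi / 2,
                             model_params(omega = 0.9, u_max = 0.1)),
                 "faster"))
})

test_that("minimal-time estimate and boost formulas evaluate correctly", {
  p0 <- model_params(omega = 4, u_max = 0)
  expect_equal(min_time_estimate(0, 3, 2, -pi / 2, p0), 3)
  # minimised over launch heights at 2/k
  p <- model_params(omega = 4, u_max = 5)
  zz <- seq(1.2, 5, length.out = 120)
  tm <- vapply(zz, function(z) min_time_estimate(0, 2 * pi, z, -pi / 2, p),
               numeric(1))
  expect_equal(zz[which.min(tm)], 2, tolerance = 0.05)

  expect_equal(boost(1, 1), 2 * exp(-2) / pi)
  expect_equal(boost(0, 1), 0)
  # linear in u_max / v
  expect_equal(boost(5, 1), 5 * boost(1, 1))
  expect_equal(boost(3, 2), boost(1.5, 1))
  expect_error(boost(1, 0), "v > 0")
})

test_that("constant-control horizontal motion solves the frozen dynamics", {
  p <- model_params(omega = 4, u_max = 5)
  th0 <- -pi / 2
  z0 <- distance_for_speed(0.62, 5, 1)
  V0 <- characteristic_speed(z0, 5, 1)
  T0 <- 0.2
  tt <- seq(0, 3, length.out = 601)
  xcf <- constant_control_x(tt, T0, th0, z0, p)
  ode <- deSolve::ode(y = xcf[1], times = tt,
                      func = function(t, y, parms)
                        list(-p$v * sin(th0) + V0 * sin(p$k * y - p$omega * t)),
                      parms = NULL, rtol = 1e-12, atol = 1e-12)
  expect_lt(max(abs(ode[, 2] - xcf)), 1e-6)
  # continuity across tangent branch cuts
  expect_lt(max(abs(diff(xcf))), 0.05)
  # V0 = 0 limit: uniform drift at the free speed
  p0 <- model_params(omega = 4, u_max = 0)
  x0cf <- constant_control_x(tt, 0, th0, 2, p0)
  expect_equal(x0cf - x0cf[1], -1 * sin(th0) * tt, tolerance = 1e-12)
})

test_that("per-cell flow displacement approaches 2 V0 / omega for weak flow", {
  om <- 4
  p <- model_params(omega = om, u_max = 0.4)
  th0 <- -pi / 2
  z0 <- 2
  V0 <- characteristic_speed(z0, p$u_max, 1)  # small, negative
  tt <- seq(0, 6, length.out = 24001)
  x <- constant_control_x(tt, 0, th0, z0, p)
  y <- x - om * tt  # phase; crossings of multiples of pi bound the cells
  crossings <- which(diff(floor(y / pi)) != 0)
  i1 <- crossings[2]; i2 <- crossings[3]
  dx_flow <- (x[i2] - x[i1]) - (-sin(th0)) * (tt[i2] - tt[i1])
  expect_equal(abs(dx_flow), 2 * abs(V0) / om, tolerance = 0.1)
})

test_that("height back-solving inverts the characteristic speed", {
  zf <- distance_for_speed(0.62, 5, 1, "far")
  zn <- distance_for_speed(0.62, 5, 1, "near")
  expect_gt(zf, 2)
  expect_lt(zn, 2)
  expect_equal(abs(characteristic_speed(zf, 5, 1)), 0.62, tolerance = 1e-9)
  expect_equal(abs(characteristic_speed(zn, 5, 1)), 0.62, tolerance = 1e-9)
  est <- transport_estimate(0, 2 * pi, zf, -pi / 2,
                            model_params(omega = 4, u_max = 5))
  expect_equal(est$V0, -0.62, tolerance = 1e-9)
  expect_equal(est$boost, est$v_flow)
  expect_equal(est$T_min, 2 * pi / (1 + est$v_flow))
})
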