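test_that("linearisation along the reference matches finite differences", {
  p <- model_params(omega = 4, u_max = 5)
  X0 <- swimmer_state(0.3, 2, -pi / 4)
  for (t0 in c(0, 0.37, 1.9)) {
    lin <- linearize(p, X0, t0)
    fd <- fd_dynamics_jacobian(p, as.numeric(unclass(lin$Xref)), 0, t0)
    expect_lt(max(abs(lin$A - fd$A)), 1e-6)
    expect_lt(max(abs(lin$B - fd$B)), 1e-6)
    # third row of B is the angular response per unit amplitude
    k <- p$k
    expect_equal(lin$B[3],
                 k / 2 * exp(-k * lin$Xref[["z"]]) *
                   sin(k * lin$Xref[["x"]] - p$omega * t0),
                 tolerance = 1e-12)
  }
  pint <- model_params(omega = 4, u_max = 5, B2 = 10,
                       include_wall_interaction = TRUE)
  expect_error(linearize(pint, X0, 0), "interaction")
})

test_that("analytic Kalman blocks match their finite-difference construction", {
  p <- model_params(k = 1.2, omega = 5, u_max = 3)
  X0 <- swimmer_state(-0.4, 1.8, 0.6)
  for (t0 in c(0.1, 0.8, 2.3)) {
    KB <- kalman_blocks(p, X0, t0)
    KBfd <- fd_kalman_blocks(p, X0, t0)
    expect_lt(max(abs(KB - KBfd)), 1e-5)
  }
  # k = 0: no rotational actuation, third row vanishes, matrix singular
  p0 <- model_params(k = 0, omega = 2, u_max = 1)
  KB0 <- kalman_blocks(p0, X0, 0.5)
  expect_equal(KB0[3, ], c(B = 0, B1 = 0, B2 = 0))
  expect_equal(det(KB0), 0)
})

test_that("closed-form determinant equals det of the Kalman blocks", {
  set.seed(33)
  n_ok <- 0
  for (i in 1:50) {
    p <- model_params(v = runif(1, 0.3, 2), k = runif(1, 0.5, 2),
                      omega = runif(1, 2, 10), u_max = 1)
    th0 <- runif(1, -pi, pi)
    # avoid the structural degeneracies for this comparison
    if (abs(cos(th0)) < 0.1) next
    if (abs(p$omega + p$k * p$v * sin(th0)) < 0.1) next
    X0 <- swimmer_state(runif(1, -3, 3), runif(1, 0.5, 4), th0)
    t0 <- runif(1, 0, 3)
    d_closed <- controllability_determinant(p, X0, t0)
    d_blocks <- det(kalman_blocks(p, X0, t0))
    d_fd <- det(fd_kalman_blocks(p, X0, t0))
    expect_equal(d_blocks, d_closed, tolerance = 1e-9)
    if (abs(d_closed) > 1e-12) {
      expect_equal(d_fd / d_closed, 1, tolerance = 1e-5)
      n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok, 40)
})

test_that("determinant vanishes identically under each structural degeneracy", {
  tt <- seq(0, 5, length.out = 400)
  X0 <- swimmer_state(0.4, 2, -pi / 3)
  # v = 0: passive particle
  expect_equal(max(abs(controllability_determinant(
    model_params(v = 0, omega = 4, u_max = 1), X0, tt))), 0)
  # k = 0: uniformly sliding wall
  expect_equal(max(abs(controllability_determinant(
    model_params(k = 0, omega = 4, u_max = 1), X0, tt))), 0)
  # comoving wave: omega + k v sin(theta0) = 0
  th0 <- -pi / 6
  om <- -sin(th0)  # with k = v = 1
  expect_lt(max(abs(controllability_determinant(
    model_params(omega = om, u_max = 1), X0 = swimmer_state(0, 2, th0), tt))),
    1e-14)
  # wall-parallel initial orientation: cos(theta0) = 0
  expect_lt(max(abs(controllability_determinant(
    model_params(omega = 4, u_max = 1), swimmer_state(0, 2, -pi / 2), tt))),
    1e-14)
  # and a generic instance does NOT vanish
  expect_gt(max(abs(controllability_determinant(
    model_params(omega = 4, u_max = 1), swimmer_state(0, 2, -pi / 4), tt))),
    1e-6)
})

test_that("zeros of the determinant are isolated in non-degenerate cases", {
  p <- model_params(omega = 4, u_max = 1)
  X0 <- swimmer_state(0, 2, -pi / 4)
  tt <- seq(0, 6, length.out = 4000)
  dd <- controllability_determinant(p, X0, tt)
  scale <- max(abs(dd))
  # no interval of zeros: no two consecutive grid samples both ~ 0
  tiny <- abs(dd) < 1e-9 * scale
  expect_false(any(tiny[-1] & tiny[-length(tiny)]))
  # and it does change sign (so zeros exist and are crossed transversally)
  expect_true(any(dd[-1] * dd[-length(dd)] < 0))
})

test_that("degeneracy classification gives the right flags and verdicts", {
  ok <- classify_degeneracies(model_params(omega = 4, u_max = 1),
                              swimmer_state(0, 2, -pi / 4))
  expect_true(ok$controllable)
  expect_length(ok$degeneracies, 0)

  r1 <- classify_degeneracies(model_params(v = 0, omega = 4, u_max = 1),
                              swimmer_state(0, 2, -pi / 4))
  expect_false(r1$controllable)
  expect_true("v_zero" %in% r1$degeneracies)

  # wall-parallel heading: proportional translational/rotational response
  r2 <- classify_degeneracies(model_params(omega = 4, u_max = 1),
                              swimmer_state(0, 2, -pi / 2))
  expect_false(r2$controllable)
  expect_true("theta0_parallel_zero" %in% r2$degeneracies)
  expect_equal(r2$omega_c, 4 - 1)

  # comoving wave front
  r3 <- classify_degeneracies(model_params(omega = 0.5, u_max = 1),
                              swimmer_state(0, 2, asin(-0.5)))
  expect_true("omega_c_zero" %in% r3$degeneracies)
})
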