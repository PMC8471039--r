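test_that("wall flow matches the closed form and its cell structure", {
  p <- model_params(omega = 1, u_max = 1)
  f0 <- wall_flow(0, 0, 0, 1, p)
  expect_equal(unlist(f0), c(Ux = 0, Uz = 0, Omega_y = 0))
  # horizontal component vanishes on the cell-reversal height z = 1/k
  expect_equal(wall_flow(c(0.3, 1.7, 9), 1, 0.4, 2, p)$Ux, rep(0, 3))
  f <- wall_flow(pi / 2, 2, 0, 1, p)
  expect_equal(f$Ux, -exp(-2))
  expect_equal(f$Uz, 0, tolerance = 1e-12)
  expect_equal(f$Omega_y, exp(-2) / 2)
  # no-penetration: vertical velocity vanishes identically on the wall
  expect_equal(wall_flow(seq(-5, 5, 0.37), 0, 1.3, 4, p)$Uz,
               rep(0, length(seq(-5, 5, 0.37))))
  # flow cells of width pi/k rotate alternately: Ux changes sign across
  # cell borders kx - wt = n pi
  pk <- model_params(k = 2, omega = 3, u_max = 1)
  t0 <- 0.7
  border <- (2 * pi + 3 * t0) / 2  # kx - wt = 2 pi
  ux1 <- wall_flow(border - 0.1, 0.2, t0, 1, pk)$Ux
  ux2 <- wall_flow(border + 0.1, 0.2, t0, 1, pk)$Ux
  expect_lt(ux1 * ux2, 0)
  expect_error(wall_flow(0, -0.1, 0, 1, p), "non-negative")
})

test_that("wall flow is incompressible (finite-difference divergence)", {
  p <- model_params(k = 1.3, omega = 2.1, u_max = 1)
  set.seed(11)
  xs <- runif(120, -10, 10)
  zs <- runif(120, 0.1, 6)
  ts <- runif(120, 0, 10)
  h <- 1e-5
  div <- (wall_flow(xs + h, zs, ts, 1, p)$Ux -
            wall_flow(xs - h, zs, ts, 1, p)$Ux) / (2 * h) +
    (wall_flow(xs, zs + h, ts, 1, p)$Uz -
       wall_flow(xs, zs - h, ts, 1, p)$Uz) / (2 * h)
  expect_lt(max(abs(div)), 1e-6)
})

test_that("free velocity and squirmer-wall interaction evaluate correctly", {
  expect_equal(unlist(free_velocity(0, 1)), c(Ux = 0, Uz = 1))
  fv <- free_velocity(-pi / 2, 1)  # heading along +x
  expect_equal(fv$Ux, 1)
  expect_equal(fv$Uz, 0, tolerance = 1e-15)
  expect_equal(free_velocity(pi, 2)$Uz, -2)

  # neutral squirmer: no wall effect at leading order
  s0 <- squirmer_wall_velocity(0.7, 1.1, 2, 0)
  expect_equal(unlist(s0), c(Ux = 0, Uz = 0, Omega_y = 0))
  s1 <- squirmer_wall_velocity(1, -pi / 2, 1, 16)
  expect_equal(s1$Ux, 0, tolerance = 1e-14)
  expect_equal(s1$Uz, -9)
  expect_equal(s1$Omega_y, 0, tolerance = 1e-14)
  s2 <- squirmer_wall_velocity(2, pi / 4, 1, 40)
  expect_equal(s2$Ux, -0.75)
  expect_equal(s2$Omega_y, -0.375)
  # squared-angle reading has no vertical effect for wall-parallel heading
  expect_equal(squirmer_wall_velocity(1, -pi / 2, 1, 16, "squared")$Uz, 0,
               tolerance = 1e-14)
  expect_error(squirmer_wall_velocity(0, 0, 1, 1), "positive")
})

test_that("state derivative is the sum of its parts and affine in u", {
  p <- model_params(omega = 4, u_max = 5, B2 = 30, a = 0.5,
                    include_wall_interaction = TRUE)
  st <- swimmer_state(0.4, 1.7, 0.9)
  t0 <- 0.3; u0 <- 2.2
  d <- state_derivative(st, u0, t0, p)
  fr <- free_velocity(0.9, p$v)
  wf <- wall_flow(0.4, 1.7, t0, u0, p)
  sq <- squirmer_wall_velocity(1.7, 0.9, 0.5, 30)
  expect_equal(unname(d),
               c(fr$Ux + wf$Ux + sq$Ux, fr$Uz + wf$Uz + sq$Uz,
                 wf$Omega_y + sq$Omega_y))
  # affine in u: d(u) - d(0) scales linearly with u
  d0 <- state_derivative(st, 0, t0, p)
  d1 <- state_derivative(st, 1, t0, p)
  expect_equal(unname(d - d0), unname(u0 * (d1 - d0)), tolerance = 1e-12)
  # no actuation, neutral swimmer: straight-line free swimming
  pn <- model_params(omega = 4, u_max = 5)
  dn <- state_derivative(swimmer_state(1, 2, 0.3), 0, 5, pn)
  expect_equal(unname(dn), c(-sin(0.3), cos(0.3), 0))
  expect_warning(state_derivative(st, 99, 0, p), "outside")
})

test_that("analytic Jacobian of the dynamics matches finite differences", {
  set.seed(21)
  for (inter in c(FALSE, TRUE)) {
    p <- model_params(k = 1.4, omega = 5, u_max = 5, B2 = -25, a = 0.4,
                      include_wall_interaction = inter)
    for (i in 1:10) {
      st <- c(runif(1, -5, 5), runif(1, 0.4, 4), runif(1, -pi, pi))
      u <- runif(1, -5, 5)
      t0 <- runif(1, 0, 5)
      J <- wallswim:::dynamics_jacobian(st, u, t0, p)
      Jfd <- fd_dynamics_jacobian(p, st, u, t0)
      expect_lt(max(abs(J$A - Jfd$A)), 1e-6)
      expect_lt(max(abs(J$B - Jfd$B)), 1e-6)
    }
  }
})

test_that("integrator reproduces the free-swimming straight line", {
  p <- model_params(omega = 4, u_max = 5)
  X0 <- swimmer_state(0.5, 2, 0.7)
  tr <- integrate_swimmer(p, 0, X0, 2)
  ref <- reference_trajectory(X0, tr$t, p)
  expect_lt(max(abs(tr$x - ref[, "x"])), 1e-7)
  expect_lt(max(abs(tr$z - ref[, "z"])), 1e-7)
  expect_equal(tr$theta, ref[, "theta"], tolerance = 1e-9)
  expect_true(all(diff(tr$t) > 0))
  expect_false(attr(tr, "crashed"))
})

test_that("passive particle under constant wave matches a fine-step oracle", {
  # v = 0: advection along a single unsteady streamline pattern
  p <- model_params(v = 0, omega = 3, u_max = 1.5)
  X0 <- swimmer_state(0.2, 1.4, 0.5)
  Tend <- 0.5
  tr <- integrate_swimmer(p, 1.5, X0, Tend)
  # explicit first-order oracle at dt = 1e-5
  y <- as.numeric(unclass(X0))
  dt <- 1e-5
  for (i in seq_len(Tend / dt)) {
    y <- y + dt * state_derivative(y, 1.5, (i - 1) * dt, p)
  }
  n <- nrow(tr)
  expect_lt(max(abs(c(tr$x[n], tr$z[n], tr$theta[n]) - y)), 1e-4)
})

test_that("integration stops with a crash flag when the wall is reached", {
  p <- model_params(omega = 4, u_max = 5)
  # drive the swimmer down with the vertical-authority bang policy
  ctrl <- function(t, s) 5 * tanh(100 * cos(s[1] - 4 * t))  # smooth bang
  tr <- integrate_swimmer(p, ctrl, swimmer_state(0, 0.8, pi), 5)
  expect_true(attr(tr, "crashed"))
  expect_lt(abs(min(tr$z) - p$crash_threshold), 1e-6)
  expect_lt(attr(tr, "crash_time"), 5)
})
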