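test_that("Hamiltonian, switching function and bang-bang law are consistent", {
  p <- model_params(omega = 4, u_max = 5)
  st <- swimmer_state(0.7, 1.9, -1.1)
  # zero costate, normal multiplier
  expect_equal(hamiltonian(st, adjoint_state(0, 0, 0), 2, 0.4, p), -1)
  # u = 0, flow-free part only
  pj <- adjoint_state(0.3, -0.8, 1.2)
  H0 <- hamiltonian(st, pj, 0, 0.4, p)
  expect_equal(H0, 1 * (-0.8 * cos(-1.1) - 0.3 * sin(-1.1)) - 1,
               tolerance = 1e-12)
  # H(u) - H(0) = u * h for any u: the Hamiltonian is affine in the control
  set.seed(7)
  for (i in 1:25) {
    st <- c(runif(1, -4, 4), runif(1, 0.3, 4), runif(1, -pi, pi))
    pv <- c(rnorm(3), -1)
    u <- runif(1, -5, 5)
    t0 <- runif(1, 0, 5)
    h <- switching_function(st, pv, t0, p)
    expect_equal(hamiltonian(st, pv, u, t0, p) -
                   hamiltonian(st, pv, 0, t0, p), u * h, tolerance = 1e-12)
  }
  # switching function decays away from the wall
  expect_lt(abs(switching_function(c(1, 40, 0), c(1, 1, 1, -1), 0, p)), 1e-15)
  # bang-bang law
  expect_equal(bang_bang(-0.3, -5, 5), -5)
  expect_equal(bang_bang(1e-9, -5, 5), 5)
  expect_equal(bang_bang(0, -5, 5), 0)
  expect_equal(bang_bang(c(-1, 0, 2), -3, 3), c(-3, 0, 3))
})

test_that("adjoint equations are the negative transposed Jacobian action", {
  p <- model_params(omega = 4, u_max = 5)
  set.seed(9)
  for (i in 1:10) {
    st <- c(runif(1, -4, 4), runif(1, 0.3, 4), runif(1, -pi, pi))
    pv <- rnorm(3)
    u <- runif(1, -5, 5)
    t0 <- runif(1, 0, 5)
    dp <- adjoint_derivative(st, c(pv, -1), u, t0, p)
    # oracle: central differences of the Hamiltonian in the state
    eps <- 1e-6
    dH <- vapply(1:3, function(j) {
      sp <- st; sm <- st
      sp[j] <- sp[j] + eps; sm[j] <- sm[j] - eps
      (hamiltonian(sp, c(pv, -1), u, t0, p) -
         hamiltonian(sm, c(pv, -1), u, t0, p)) / (2 * eps)
    }, numeric(1))
    expect_equal(unname(dp), -dH, tolerance = 1e-5)
  }
  # linear in the costate
  expect_equal(unname(adjoint_derivative(c(0, 2, 1), c(0, 0, 0, -1), 1, 0, p)),
               c(0, 0, 0))
  # free swimming: position costates are conserved
  dp0 <- adjoint_derivative(c(0, 2, 1), c(0.4, 0.7, -0.2, -1), 0, 0, p)
  expect_equal(unname(dp0[1:2]), c(0, 0))
})

test_that("switch-time extraction recovers square-wave switching", {
  p <- model_params(omega = 4, u_max = 5)
  tt <- seq(0, 10, by = 0.002)
  tau <- 0.8
  u <- 5 * sign(sin(pi * tt / tau))
  tr <- wallswim:::new_trajectory(
    data.frame(t = tt, x = tt, z = 2, theta = 0, u = u), p)
  sw <- extract_switch_times(tr)
  expect_equal(attr(sw, "mean_spacing"), tau, tolerance = 0.01)
  trc <- wallswim:::new_trajectory(
    data.frame(t = tt, x = tt, z = 2, theta = 0, u = 5), p)
  expect_warning(swc <- extract_switch_times(trc), "fewer than two")
  expect_length(swc, 0)
})

test_that("height-change steering (Problem 3) reaches its target quickly", {
  p <- model_params(omega = 4, u_max = 5)
  pb <- optimal_control_problem(3, swimmer_state(0, 2, -pi / 2), p, z1 = 1)
  sol <- solve_time_optimal(pb)
  tr <- sol$trajectory
  expect_equal(tr$z[nrow(tr)], 1, tolerance = 1e-6)
  # actuation must beat pure drift: free swimming cannot change z at all
  # from a wall-parallel heading, and the vertical flow speed bounds the
  # approach rate from above
  expect_lt(sol$T_min, 5)
  expect_gt(sol$T_min, (2 - 1) / (p$u_max * exp(-1) + p$v))
  # bang-bang control by construction
  expect_true(all(abs(tr$u) == p$u_max))
})

test_that("enlarging the control set never slows the transport problem", {
  sc <- scenario_preset("fig3a_w4")
  sol5 <- fig3a_solution()
  p25 <- model_params(omega = 4, u_max = 2.5)
  pb <- optimal_control_problem(1, sc$X0, p25, x1 = sc$problem$x1)
  sol25 <- solve_time_optimal(pb)
  expect_gte(sol25$T_min, sol5$T_min)
  # and any actuation beats none (free transit takes x1/v)
  expect_lte(sol5$T_min, sc$problem$x1)
})

test_that("no actuation reduces Problem 1 to the free straight line", {
  p0 <- model_params(omega = 4, u_max = 0)
  pb <- optimal_control_problem(1, swimmer_state(0, 2, -pi / 2), p0, x1 = 3)
  sol <- solve_time_optimal(pb)
  expect_equal(sol$T_min, 3)
  expect_length(sol$switch_times, 0)
})

test_that("structurally uncontrollable scenarios are refused", {
  p <- model_params(v = 0, omega = 4, u_max = 5)
  pb <- optimal_control_problem(1, swimmer_state(0, 2, -pi / 2), p, x1 = 3)
  expect_error(solve_time_optimal(pb), "uncontrollable")
  pa <- model_params(omega = 4, u_max = 5, u_min = 0)
  pb2 <- optimal_control_problem(1, swimmer_state(0, 2, -pi / 2), pa, x1 = 3)
  expect_error(solve_time_optimal(pb2), "symmetric")
})

test_that("a costate reproducing the converged switching pattern exists", {
  sol <- fig3a_solution()
  pc <- pmp_switching_consistency(sol)
  expect_gte(pc$agreement, 0.9)
})
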