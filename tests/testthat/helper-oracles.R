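# Shared oracles and cached expensive solves.  The cache lives for the test
# session so several test files can reuse the same converged solutions.

.ws_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ws_test_cache)) {
    assign(key, force(expr), envir = .ws_test_cache)
  }
  get(key, envir = .ws_test_cache)
}

# central finite differences of the dynamics, the independent Jacobian oracle
fd_dynamics_jacobian <- function(params, state, u, t, eps = 1e-6) {
  A <- matrix(0, 3, 3)
  st <- as.numeric(state)
  for (j in 1:3) {
    sp <- st; sm <- st
    sp[j] <- sp[j] + eps
    sm[j] <- sm[j] - eps
    A[, j] <- (state_derivative(sp, u, t, params) -
                 state_derivative(sm, u, t, params)) / (2 * eps)
  }
  B <- (state_derivative(st, u + eps, t, params) -
          state_derivative(st, u - eps, t, params)) / (2 * eps)
  list(A = A, B = B)
}

# Kalman blocks built purely from finite differences along the reference;
# fourth-order stencils keep the truncation error well below the 1e-5
# comparison tolerance even at high wave frequencies
fd_kalman_blocks <- function(params, X0, t, eps = 1e-4) {
  d4 <- function(f, tt) {
    (f(tt - 2 * eps) - 8 * f(tt - eps) + 8 * f(tt + eps) - f(tt + 2 * eps)) /
      (12 * eps)
  }
  Bf <- function(tt) linearize(params, X0, tt)$B
  Af <- function(tt) linearize(params, X0, tt)$A
  B1f <- function(tt) d4(Bf, tt) - Af(tt) %*% Bf(tt)
  B2 <- d4(function(tt) as.numeric(B1f(tt)), t) - Af(t) %*% B1f(t)
  cbind(Bf(t), as.numeric(B1f(t)), as.numeric(B2))
}

# frozen-state simulation of the cell-synchronised bang-bang strategy:
# the independent oracle for the flow gain and the switch cadence
frozen_transport_oracle <- function(z0, params, T = 30, dt = 2e-4) {
  k <- params$k; om <- params$omega
  x <- 0; t <- 0
  sw <- numeric(0)
  nstep <- ceiling(T / dt)
  fwd <- sign(1 - k * z0)  # sign making every half-cell favourable
  for (i in seq_len(nstep)) {
    s <- sin(k * x - om * t)
    u <- fwd * params$u_max * sign(s)
    prev <- s
    xd <- params$v + u * exp(-k * z0) * (1 - k * z0) * sin(k * x - om * t)
    x <- x + dt * xd
    t <- t + dt
    if (sin(k * x - om * t) * prev < 0) sw <- c(sw, t)
  }
  list(v_flow = x / T - params$v, T_switch = mean(diff(sw)))
}

# robust cadence of a bang-bang solution: the typical inter-switch interval,
# discarding the short double-switch corrections used for height regulation
steady_cadence <- function(solution) {
  d <- diff(extract_switch_times(solution$trajectory))
  d <- d[d > 0.5 * max(d)]
  stats::median(d)
}

fig3a_solution <- function() {
  cached("fig3a_full", {
    sc <- scenario_preset("fig3a_w4")
    solve_time_optimal(sc$problem)
  })
}

fig3_grid_names <- c("fig3a_w4", "fig3a_w8", "fig3a_w12",
                     "fig3b_w4", "fig3b_w8", "fig3b_w12")

fig3_solution <- function(nm, mode = c("full", "nearref")) {
  mode <- match.arg(mode)
  if (nm == "fig3a_w4" && mode == "full") return(fig3a_solution())
  cached(paste(nm, mode, sep = "_"), {
    sc <- scenario_preset(nm)
    opts <- if (mode == "full") ocp_options() else
      ocp_options(seed_families = c("synchronised", "cadence"))
    solve_time_optimal(sc$problem, options = opts)
  })
}

fig4_solution <- function(nm) {
  cached(nm, solve_time_optimal(scenario_preset(nm)$problem))
}

fig5_run <- function(nm) {
  cached(paste0(nm, "_run"), {
    sc <- scenario_preset(nm)
    run_policy_experiment(sc$X0, sc$horizon, sc$policy, sc$params)
  })
}
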