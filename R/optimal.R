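#' Adjoint (costate) vector of the maximum principle
#'
#' @param px,pz,ptheta costates conjugate to \code{x}, \code{z}, \code{theta}.
#' @param p0 abnormal multiplier (<= 0; -1 for normal minimum-time arcs).
#' @return A \code{ws_adjoint} named numeric vector.
#' @export
adjoint_state <- function(px, pz, ptheta, p0 = -1) {
  stopifnot(p0 <= 0)
  structure(c(px = px, pz = pz, ptheta = ptheta, p0 = p0),
            class = "ws_adjoint")
}

as_ws_adjoint <- function(p) {
  if (inherits(p, "ws_adjoint")) return(p)
  p <- unlist(p, use.names = FALSE)
  if (length(p) == 3L) p <- c(p, -1)
  adjoint_state(p[1], p[2], p[3], p[4])
}

#' Pontryagin Hamiltonian of the minimum-time problem
#'
#' \eqn{H = p \cdot f(X, u, t) + p_0}, built directly from
#' \code{\link{state_derivative}} so that it is exact for whatever dynamics
#' are enabled (including the squirmer-wall term).
#'
#' @param state a \code{\link{swimmer_state}}.
#' @param adjoint a \code{\link{adjoint_state}}.
#' @param u control value.
#' @param t time.
#' @param params a \code{\link{model_params}} object.
#' @return Scalar Hamiltonian value.
#' @export
hamiltonian <- function(state, adjoint, u, t, params) {
  p <- as_ws_adjoint(adjoint)
  f <- state_derivative(state, u, t, params)
  sum(p[1:3] * f) + p[["p0"]]
}

#' Switching function of the bang-bang law
#'
#' Coefficient of the control in the Hamiltonian,
#' \eqn{h(p, X) = \partial H/\partial u = p \cdot B(X, t)}:
#' \deqn{h = e^{-kz}\left[\left(p_x (1 - kz) + \tfrac{k}{2} p_\theta\right)
#'   \sin(kx - \omega t) - p_z k z \cos(kx - \omega t)\right].}
#' Its sign selects the active control bound.
#'
#' @inheritParams hamiltonian
#' @return Scalar switching-function value.
#' @export
switching_function <- function(state, adjoint, t, params) {
  p <- as_ws_adjoint(adjoint)
  B <- dynamics_jacobian(state, 0, t, params)$B
  sum(p[1:3] * B)
}

#' Bang-bang control law
#'
#' Maximises the control-affine Hamiltonian pointwise:
#' \code{u_min} when the switching function is negative, \code{u_max} when
#' positive, and 0 on the (measure-zero) switching set.
#'
#' @param h switching-function value (vectorised).
#' @param u_min,u_max control bounds.
#' @return Control value(s).
#' @export
bang_bang <- function(h, u_min, u_max) {
  ifelse(h > 0, u_max, ifelse(h < 0, u_min, 0))
}

#' Adjoint equations
#'
#' Costate dynamics of the maximum principle,
#' \eqn{\dot p = -\left(\partial f/\partial X\right)^{T} p} (the
#' maximisation-consistent sign convention).  \code{p0} is constant.
#'
#' @inheritParams hamiltonian
#' @param adjoint current costate.
#' @return Named numeric vector \code{c(dpx, dpz, dptheta)}.
#' @export
adjoint_derivative <- function(state, adjoint, u, t, params) {
  p <- as_ws_adjoint(adjoint)
  A <- dynamics_jacobian(state, u, t, params)$A
  d <- -as.numeric(t(A) %*% p[1:3])
  names(d) <- c("dpx", "dpz", "dptheta")
  d
}

#' Minimum-time steering problem
#'
#' Defines one of the three guidance objectives for the wall-driven swimmer:
#' \describe{
#'   \item{Problem 1}{wall-parallel displacement: reach \code{x = x1} with the
#'     height back at its initial value \code{z0}; final orientation free.}
#'   \item{Problem 2}{reorientation: reach \code{theta = theta1} with the
#'     height back at \code{z0}; final \code{x} free.}
#'   \item{Problem 3}{wall-distance change: reach \code{z = z1}; final
#'     \code{x} and \code{theta} free.}
#' }
#'
#' @param problem_id 1, 2 or 3.
#' @param X0 initial \code{\link{swimmer_state}}.
#' @param params a \code{\link{model_params}} object.
#' @param x1 target horizontal position (Problem 1).
#' @param theta1 target orientation (Problem 2).
#' @param z1 target height (Problem 3).
#' @return A \code{ws_ocp} list.
#' @export
optimal_control_problem <- function(problem_id, X0, params,
                                    x1 = NULL, theta1 = NULL, z1 = NULL) {
  stopifnot(problem_id %in% 1:3)
  X0 <- as_ws_state(X0)
  if (problem_id == 1) {
    stopifnot(!is.null(x1), x1 > X0[["x"]])
  } else if (problem_id == 2) {
    stopifnot(!is.null(theta1), abs(theta1 - X0[["theta"]]) > 1e-12)
  } else {
    stopifnot(!is.null(z1), z1 > 0, abs(z1 - X0[["z"]]) > 1e-12)
  }
  structure(list(problem_id = problem_id, X0 = X0, params = params,
                 x1 = x1, theta1 = theta1, z1 = z1),
            class = "ws_ocp")
}

# initial bang sign that pushes the swimmer forward in its first half-cell
forward_sign <- function(X0, params, eps = 1e-6) {
  k <- params$k
  nu <- params$omega + k * params$v * sin(X0[["theta"]])
  ph <- k * X0[["x"]] - nu * eps
  s <- sin(ph)
  if (abs(s) < 1e-12) s <- -nu * eps * cos(k * X0[["x"]])
  coeff <- (1 - k * X0[["z"]]) * s
  if (abs(coeff) < .Machine$double.eps) return(1)
  sign(coeff)  # want u * coeff > 0
}

# run one phase of the z-regulated synchronised policy (compiled kernel) and
# return its contribution to a switching schedule
policy_phase <- function(X, t0, M, carrier, kappa, z_target, params, h,
                         ev = c(0, 0, 0), t_cap, dmax = 1.0) {
  r <- .ws_rollout_policy(unclass(X), t0, M, carrier, kappa, z_target, dmax,
                          params$u_max, par_vec(params), h,
                          as.integer(ev[1]), ev[2], ev[3], t_cap)
  r
}

# convert a list of (switch time, sign-after-switch) into durations + s0
schedule_to_durations <- function(sw, signs, s_first, T_end) {
  tt <- c(0, sw, T_end)
  d <- diff(tt)
  keep <- d > 1e-9
  list(d = d[keep & c(TRUE, rep(TRUE, length(d) - 1))], s0 = s_first,
       durations = d, T = T_end)
}

seed_candidates <- function(problem, options) {
  params <- problem$params
  X0 <- problem$X0
  z0 <- X0[["z"]]; th0 <- X0[["theta"]]
  k <- params$k; v <- params$v
  h <- options$h_seed
  seeds <- list()
  s_fwd <- forward_sign(X0, params)

  if (problem$problem_id == 1) {
    t_cap <- options$t_cap
    dist <- problem$x1 - X0[["x"]]
    # (a) near-reference synchronised seeds, with and without z regulation
    for (kap in if ("synchronised" %in% options$seed_families) c(0, 2) else numeric(0)) {
      M <- if (z0 > 1 / k) -1 else 1
      r <- policy_phase(X0, 0, M, 0L, kap, z0, params, h,
                        ev = c(1, problem$x1, 1), t_cap)
      if (isTRUE(r$ok) && isTRUE(r$crossed) && length(r$switch_times) >= 1) {
        sw <- r$switch_times
        seeds[[length(seeds) + 1]] <-
          list(d = diff(c(0, sw, r$T)), s0 = s_fwd,
               label = sprintf("synchronised kappa=%g", kap))
      }
    }
    # (b) uniform analytic cadence
    Ts <- tryCatch(switch_time(z0, th0, params), error = function(e) NULL)
    if ("cadence" %in% options$seed_families &&
        !is.null(Ts) && is.finite(Ts) && Ts > 0) {
      m <- ceiling(1.6 * options$t_cap_soft / Ts)
      m <- min(max(m, 4), options$max_segments)
      for (frac in c(1, 0.5)) {
        seeds[[length(seeds) + 1]] <-
          list(d = c(frac * Ts, rep(Ts, m - 1)), s0 = s_fwd,
               label = sprintf("uniform cadence frac=%g", frac))
      }
    }
    # (c) dive-surf-climb seeds: descend, surf at z_dive, climb near target
    for (z_dive in if ("dive" %in% options$seed_families)
           options$dive_heights / k else numeric(0)) {
      if (z_dive >= z0) next
      for (xmf in options$climb_margins) {
        ph1 <- policy_phase(X0, 0, 1, 1L, 0, z_dive, params, h,
                            ev = c(2, z_dive, -1), t_cap)
        if (!isTRUE(ph1$ok) || !isTRUE(ph1$crossed)) next
        X1s <- swimmer_state(ph1$state[1], ph1$state[2], ph1$state[3])
        x_margin <- xmf * (z0 - z_dive)
        M2 <- if (z_dive > 1 / k) -1 else 1
        ph2 <- policy_phase(X1s, ph1$T, M2, 0L, 2, z_dive, params, h,
                            ev = c(1, problem$x1 - x_margin, 1), t_cap)
        if (!isTRUE(ph2$ok) || !isTRUE(ph2$crossed)) next
        X2s <- swimmer_state(ph2$state[1], ph2$state[2], ph2$state[3])
        ph3 <- policy_phase(X2s, ph2$T, -1, 1L, 0, z0, params, h,
                            ev = c(1, problem$x1, 1), t_cap)
        if (!isTRUE(ph3$ok)) next
        sw <- c(ph1$switch_times, ph1$T, ph2$switch_times, ph2$T,
                ph3$switch_times)
        sw <- sort(unique(sw[sw > 1e-9 & sw < ph3$T - 1e-9]))
        seeds[[length(seeds) + 1]] <-
          list(d = diff(c(0, sw, ph3$T)), s0 = s_fwd,
               label = sprintf("dive z=%g margin=%g", z_dive, xmf))
      }
    }
  } else if (problem$problem_id == 2) {
    t_cap <- options$t_cap
    dth <- problem$theta1 - th0
    # approach-rotate-escape profiles: descend to a rotation height, rotate
    # with strong z regulation, climb back out
    for (z_rot in options$rotation_height / k) {
      if (z_rot >= z0) next
      ph1 <- policy_phase(X0, 0, 1, 1L, 0, z_rot, params, h,
                          ev = c(2, z_rot, -1), t_cap)
      if (!isTRUE(ph1$ok) || !isTRUE(ph1$crossed)) next
      if (ph1$zmin < params$crash_threshold) next
      X1s <- swimmer_state(ph1$state[1], ph1$state[2], ph1$state[3])
      ph2 <- policy_phase(X1s, ph1$T, sign(dth), 0L, 4, z_rot, params, h,
                          ev = c(3, problem$theta1, sign(dth)), t_cap,
                          dmax = 1.4)
      if (!isTRUE(ph2$ok) || !isTRUE(ph2$crossed)) next
      if (ph2$zmin < params$crash_threshold) next
      X2s <- swimmer_state(ph2$state[1], ph2$state[2], ph2$state[3])
      ph3 <- policy_phase(X2s, ph2$T, -1, 1L, 0, z0, params, h,
                          ev = c(2, z0, 1), t_cap)
      if (!isTRUE(ph3$ok)) next
      sw <- c(ph1$switch_times, ph1$T, ph2$switch_times, ph2$T,
              ph3$switch_times)
      sw <- sort(unique(sw[sw > 1e-9 & sw < ph3$T - 1e-9]))
      seeds[[length(seeds) + 1]] <-
        list(d = diff(c(0, sw, ph3$T)), s0 = s_fwd,
             label = sprintf("approach-rotate-escape z=%g", z_rot))
    }
    # composite profile for large rotations: the swimmer gains height while
    # rotating through wall-normal headings, so alternate capped rotation
    # stints with re-descents until the target heading is reached
    for (z_rot in options$rotation_height / k) {
      if (z_rot >= z0) next
      ph <- policy_phase(X0, 0, 1, 1L, 0, z_rot, params, h,
                         ev = c(2, z_rot, -1), t_cap)
      if (!isTRUE(ph$ok) || !isTRUE(ph$crossed) ||
          ph$zmin < params$crash_threshold) next
      sw <- c(ph$switch_times, ph$T)
      Xc <- swimmer_state(ph$state[1], ph$state[2], ph$state[3])
      tcur <- ph$T
      done <- FALSE
      bad <- FALSE
      for (stint in 1:30) {
        ph <- policy_phase(Xc, tcur, sign(dth), 0L, 4, z_rot, params, h,
                           ev = c(3, problem$theta1, sign(dth)),
                           min(t_cap, tcur + 1.2), dmax = 1.4)
        if (!isTRUE(ph$ok) || ph$zmin < params$crash_threshold) {
          bad <- TRUE
          break
        }
        sw <- c(sw, ph$switch_times, ph$T)
        Xc <- swimmer_state(ph$state[1], ph$state[2], ph$state[3])
        tcur <- ph$T
        if (isTRUE(ph$crossed)) {
          done <- TRUE
          break
        }
        if (Xc[["z"]] > z_rot + 0.3 / k) {
          ph <- policy_phase(Xc, tcur, 1, 1L, 0, z_rot, params, h,
                             ev = c(2, z_rot, -1), t_cap)
          if (!isTRUE(ph$ok) || !isTRUE(ph$crossed) ||
              ph$zmin < params$crash_threshold) {
            bad <- TRUE
            break
          }
          sw <- c(sw, ph$switch_times, ph$T)
          Xc <- swimmer_state(ph$state[1], ph$state[2], ph$state[3])
          tcur <- ph$T
        }
      }
      if (bad || !done) next
      ph <- policy_phase(Xc, tcur, -1, 1L, 0, z0, params, h,
                         ev = c(2, z0, 1), t_cap)
      if (!isTRUE(ph$ok)) next
      sw <- c(sw, ph$switch_times)
      sw <- sort(unique(sw[sw > 1e-9 & sw < ph$T - 1e-9]))
      seeds[[length(seeds) + 1]] <-
        list(d = diff(c(0, sw, ph$T)), s0 = s_fwd,
             label = sprintf("staged rotate z=%g", z_rot))
    }
    # uniform cadence seeds at several horizons and phase offsets
    Ts <- pi / max(params$omega - k * v, params$omega / 2)
    for (Ttar in c(1, 1.8) * (2 * z0 / max(v, 0.1) + 2 * abs(dth))) {
      m <- min(max(4, ceiling(Ttar / Ts)), options$max_segments)
      for (frac in c(1, 0.5)) {
        seeds[[length(seeds) + 1]] <-
          list(d = c(frac * Ts, rep(Ts, m - 1)), s0 = 1,
               label = sprintf("uniform cadence T=%.2g frac=%g", Ttar, frac))
      }
    }
  } else {
    going_down <- problem$z1 < z0
    M <- if (going_down) 1 else -1
    r <- policy_phase(X0, 0, M, 1L, 0, problem$z1, params, h,
                      ev = c(2, problem$z1, if (going_down) -1 else 1),
                      options$t_cap)
    if (isTRUE(r$ok) && isTRUE(r$crossed)) {
      seeds[[length(seeds) + 1]] <-
        list(d = diff(c(0, r$switch_times, r$T)), s0 = M * 1,
             label = "vertical authority")
    }
    seeds[[length(seeds) + 1]] <-
      list(d = rep(pi / params$omega, min(options$max_segments, 24)),
           s0 = 1, label = "uniform cadence")
  }
  # prune: collapse ultra-short segments (merging their neighbours, which
  # preserves the sign alternation), cap the number of variables
  lapply(seeds, function(sd) {
    d <- sd$d
    repeat {
      i <- which(d < 0.02)
      i <- i[i > 1 & i < length(d)]
      if (!length(i)) break
      j <- i[1]
      d <- c(d[seq_len(j - 2)], d[j - 1] + d[j] + d[j + 1],
             d[-seq_len(j + 1)])
    }
    d <- d[d > 1e-8]
    if (length(d) > options$max_segments) d <- d[seq_len(options$max_segments)]
    sd$d <- d
    sd
  })
}

#' Default options for the time-optimal solver
#'
#' @param h integration step of the fixed-step RK4 rollouts used inside the
#'   optimiser (the reported solution is re-integrated at \code{h_fine}).
#' @param h_fine step for the final reported trajectory.
#' @param h_seed step for the heuristic seed rollouts.
#' @param tol_constraint terminal equality tolerance.
#' @param max_segments maximum number of bang segments (decision variables).
#' @param al_iterations maximum augmented-Lagrangian outer iterations.
#' @param maxit_inner L-BFGS-B iteration cap per outer iteration.
#' @param mu0 initial constraint penalty weight.
#' @param dive_heights heights (units of 1/k) for the dive-surf-climb seed
#'   family of Problem 1.
#' @param climb_margins horizontal margins (as a multiple of the dive depth)
#'   reserved for the climb phase in the dive seeds.
#' @param rotation_height heights (units of 1/k) at which the Problem-2 seeds
#'   rotate.
#' @param seed_families which deterministic seed families to refine for
#'   Problem 1: \code{"synchronised"} and \code{"cadence"} stay near the
#'   launch height (the regime the closed-form estimates describe),
#'   \code{"dive"} explores wall-skimming profiles.
#' @param z_floor path floor on z enforced by penalty; defaults to 1.2 times
#'   the crash threshold so that converged solutions graze the floor from
#'   above without crashing.
#' @param t_cap_factor multiple of the free-swimming time used as the hard
#'   horizon cap.
#' @return Options list.
#' @export
ocp_options <- function(h = 0.004, h_fine = 0.0015, h_seed = 0.002,
                        tol_constraint = 1e-6, max_segments = 40L,
                        al_iterations = 14L, maxit_inner = 600L, mu0 = 2,
                        dive_heights = c(0.3, 0.5), climb_margins = c(1.4, 1),
                        rotation_height = c(0.5, 0.8),
                        z_floor = NULL, t_cap_factor = 3,
                        seed_families = c("synchronised", "cadence",
                                          "dive")) {
  list(h = h, h_fine = h_fine, h_seed = h_seed,
       tol_constraint = tol_constraint, max_segments = max_segments,
       al_iterations = al_iterations, maxit_inner = maxit_inner, mu0 = mu0,
       dive_heights = dive_heights, climb_margins = climb_margins,
       rotation_height = rotation_height,
       z_floor = z_floor, t_cap_factor = t_cap_factor,
       seed_families = seed_families)
}

#' Solve a minimum-time steering problem
#'
#' Direct solver for the three guidance problems.  The control is parametrised
#' by its bang-bang structure -- an initial sign and the durations of the
#' alternating \eqn{\pm u_{max}} segments -- which the maximum principle shows
#' is the form of the optimum.  The final time is free: for Problems 1 and 3
#' it is the (interpolated) first-crossing time of the target surface, for
#' Problem 2 it is the sum of the segment durations.  Remaining terminal
#' equalities are enforced by an augmented-Lagrangian outer loop around
#' box-constrained quasi-Newton (\code{optim L-BFGS-B}) over the durations,
#' and a path penalty keeps the swimmer above the wall.  A deterministic
#' family of seeds (cell-synchronised driving at the initial height, uniform
#' analytic cadence, dive-surf-climb profiles, approach-rotate-escape for
#' reorientation) is refined and the best feasible local solution returned.
#'
#' @param problem a \code{\link{optimal_control_problem}}.
#' @param options solver options from \code{\link{ocp_options}}.
#' @param verbose print per-seed progress.
#' @return A \code{ws_optimal_solution}: list with \code{T_min},
#'   \code{trajectory} (a \code{ws_trajectory}), \code{switch_times},
#'   \code{durations}, \code{s0}, \code{diagnostics}.
#' @export
solve_time_optimal <- function(problem, options = ocp_options(),
                               verbose = FALSE) {
  stopifnot(inherits(problem, "ws_ocp"))
  params <- problem$params
  if (abs(params$u_min + params$u_max) > 1e-12)
    stop("solve_time_optimal: implemented for symmetric bounds ",
         "u_min = -u_max")
  rep0 <- classify_degeneracies(params, problem$X0)
  triv <- intersect(rep0$degeneracies, c("k_zero", "v_zero"))
  if (length(triv))
    stop("solve_time_optimal: structurally uncontrollable scenario (",
         paste(triv, collapse = ", "), ")")
  X0 <- problem$X0
  z0 <- X0[["z"]]
  if (is.null(options$z_floor))
    options$z_floor <- 1.2 * params$crash_threshold
  free_T <- switch(problem$problem_id,
                   (problem$x1 - X0[["x"]]) / max(params$v, 1e-9),
                   10 * 2 * z0 / max(params$v, 1e-9) / options$t_cap_factor,
                   10 * 2 * z0 / max(params$v, 1e-9) / options$t_cap_factor)
  options$t_cap <- options$t_cap_factor * free_T
  options$t_cap_soft <- free_T

  ev <- switch(problem$problem_id,
               c(1, problem$x1, 1),
               c(0, 0, 0),
               c(2, problem$z1, if (problem$z1 < z0) -1 else 1))
  gfun <- switch(problem$problem_id,
                 function(Xf) Xf[2] - z0,
                 function(Xf) c(Xf[2] - z0, Xf[3] - problem$theta1),
                 function(Xf) numeric(0))
  ng <- length(gfun(c(0, z0, 0)))

  if (params$u_max == 0) {
    return(zero_control_solution(problem, options))
  }

  seeds <- seed_candidates(problem, options)
  if (!length(seeds))
    stop("solve_time_optimal: no admissible seed trajectory found; ",
         "the target may be unreachable from this state")

  pv <- par_vec(params)
  roll <- function(d, s0, h, record = FALSE) {
    tail <- stats::median(d[d > 0.05 * max(d, 1e-8)])
    if (!is.finite(tail) || tail <= 0) tail <- pi / params$omega
    .ws_rollout_bang(unclass(X0), d, s0, params$u_max, pv, h,
                     as.integer(ev[1]), ev[2], ev[3], options$t_cap,
                     tail, record)
  }
  evaluate <- function(d, s0, lam, mu, hstep) {
    r <- roll(pmax(d, 0), s0, hstep)
    if (!isTRUE(r$ok)) return(1e8)
    Tt <- r$T
    pen <- 0
    if (ev[1] > 0) {
      if (!isTRUE(r$crossed))
        pen <- pen + 50 * (ev[3] * (ev[2] - r$state[ev[1]]))^2 + 20
    }
    g <- gfun(r$state)
    J <- Tt + pen + 2000 * max(0, options$z_floor - r$zmin)^2
    if (ng > 0) J <- J + sum(lam * g) + mu / 2 * sum(g * g)
    if (!is.finite(J)) 1e8 else J
  }

  best <- NULL
  for (is in seq_along(seeds)) {
    sd <- seeds[[is]]
    d <- sd$d
    m <- length(d)
    lam <- rep(0, ng); mu <- options$mu0
    d_cap <- max(3 * max(d), 4)
    conv <- FALSE
    for (it in seq_len(options$al_iterations)) {
      op <- tryCatch(
        stats::nlminb(d, evaluate, s0 = sd$s0, lam = lam, mu = mu,
                      hstep = options$h, lower = rep(0, m),
                      upper = rep(d_cap, m),
                      control = list(iter.max = options$maxit_inner,
                                     eval.max = 5 * options$maxit_inner)),
        error = function(e) e)
      if (inherits(op, "error")) {
        if (verbose) message("  inner solver error: ", conditionMessage(op))
        break
      }
      d <- op$par
      r <- roll(d, sd$s0, options$h)
      if (!isTRUE(r$ok)) break
      g <- gfun(r$state)
      if (verbose)
        message(sprintf("  AL it %d: T = %.6f, |g| = %.3e, mu = %g", it,
                        r$T, if (ng > 0) max(abs(g)) else 0, mu))
      crossed_ok <- ev[1] == 0 || isTRUE(r$crossed)
      if (crossed_ok && (ng == 0 || max(abs(g)) < options$tol_constraint)) {
        conv <- TRUE
        break
      }
      if (ng > 0) {
        lam <- lam + mu * g
        mu <- min(mu * 4, 1e7)
      } else if (crossed_ok) {
        conv <- TRUE
        break
      } else break
    }
    # fine-step polish: re-solve once at the reporting resolution, then take
    # damped Newton steps on the last few durations so the terminal
    # equalities hold at the accuracy of the reported trajectory
    if (ng > 0) {
      r <- roll(d, sd$s0, options$h_fine)
      if (isTRUE(r$ok)) {
        g <- gfun(r$state)
        if (max(abs(g)) < 5e-2) {
          op <- tryCatch(
            stats::nlminb(d, evaluate, s0 = sd$s0, lam = lam,
                          mu = max(mu, 1e5), hstep = options$h_fine,
                          lower = rep(0, m), upper = rep(d_cap, m),
                          control = list(iter.max = options$maxit_inner,
                                         eval.max = 5 * options$maxit_inner)),
            error = function(e) NULL)
          if (!is.null(op)) d <- op$par
          d <- newton_terminal(d, sd$s0, roll, gfun, options)
        }
      }
    }
    r <- roll(d, sd$s0, options$h_fine)
    if (!isTRUE(r$ok)) next
    g <- gfun(r$state)
    feas <- (ev[1] == 0 || isTRUE(r$crossed)) &&
      (ng == 0 || max(abs(g)) < options$tol_constraint) &&
      r$zmin > params$crash_threshold
    viol <- if (ng > 0) max(abs(g)) else 0
    if (verbose)
      message(sprintf("seed %d (%s): T = %.5f, violation = %.2e, %s",
                      is, sd$label, r$T, viol,
                      if (feas) "feasible" else "infeasible"))
    cand <- list(d = d, s0 = sd$s0, T = r$T, g = g, feasible = feas,
                 label = sd$label, viol = viol)
    if (is.null(best)) best <- cand
    else if (feas && (!best$feasible || r$T < best$T)) best <- cand
    else if (!best$feasible && !feas && viol < best$viol) best <- cand
  }
  if (is.null(best))
    stop("solve_time_optimal: all starts failed to produce a finite rollout")
  if (!best$feasible)
    stop(sprintf(paste0("solve_time_optimal: no start met the terminal ",
                        "constraints (best violation %.3e after %d seeds); ",
                        "the target may be infeasible within the horizon cap ",
                        "%.3g"), best$viol, length(seeds), options$t_cap))

  # final accurate reintegration and trajectory assembly
  rf <- roll(best$d, best$s0, options$h_fine, record = TRUE)
  tr <- rf$traj
  df <- data.frame(t = tr[, 1], x = tr[, 2], z = tr[, 3], theta = tr[, 4],
                   u = tr[, 5])
  Tmin <- rf$T
  cs <- cumsum(best$d[best$d > 1e-10])
  sw <- cs[cs < Tmin - 1e-9]
  traj <- new_trajectory(df, params,
                         crashed = rf$zmin <= params$crash_threshold,
                         switch_times = sw)
  structure(list(T_min = Tmin, trajectory = traj, switch_times = sw,
                 durations = best$d, s0 = best$s0, problem = problem,
                 diagnostics = list(status = "converged",
                                    constraint_violation = best$viol,
                                    seed = best$label,
                                    n_starts = length(seeds),
                                    n_segments = length(best$d),
                                    zmin = rf$zmin)),
            class = "ws_optimal_solution")
}

# damped Newton correction on the trailing durations, driving the terminal
# equality residuals to tolerance without leaving the converged local basin
newton_terminal <- function(d, s0, roll, gfun, options) {
  r <- roll(d, s0, options$h_fine)
  if (!isTRUE(r$ok)) return(d)
  g <- gfun(r$state)
  ng <- length(g)
  if (ng == 0 || max(abs(g)) < 0.5 * options$tol_constraint) return(d)
  nz <- which(d > 5e-3)
  if (length(nz) < ng + 1) return(d)
  idx <- utils::tail(nz, ng + 1)
  for (it in 1:20) {
    r <- roll(d, s0, options$h_fine)
    if (!isTRUE(r$ok)) return(d)
    g <- gfun(r$state)
    if (max(abs(g)) < 0.5 * options$tol_constraint) break
    J <- matrix(0, ng, length(idx))
    fd <- 1e-6
    for (j in seq_along(idx)) {
      dp <- d
      dp[idx[j]] <- dp[idx[j]] + fd
      rp <- roll(dp, s0, options$h_fine)
      if (!isTRUE(rp$ok)) return(d)
      J[, j] <- (gfun(rp$state) - g) / fd
    }
    step <- tryCatch(qr.solve(J, -g), error = function(e) NULL)
    if (is.null(step)) break
    sc <- 1
    repeat {
      dn <- d
      dn[idx] <- pmax(0, dn[idx] + sc * step)
      rn <- roll(dn, s0, options$h_fine)
      gn <- if (isTRUE(rn$ok)) gfun(rn$state) else Inf
      if (all(is.finite(gn)) && max(abs(gn)) < max(abs(g))) {
        d <- dn
        break
      }
      sc <- sc / 2
      if (sc < 1e-4) return(d)
    }
  }
  d
}

zero_control_solution <- function(problem, options) {
  # no actuation available: only the free straight line is admissible
  params <- problem$params
  X0 <- problem$X0
  if (problem$problem_id != 1)
    stop("solve_time_optimal: u_max = 0 cannot change height or orientation")
  vx <- -params$v * sin(X0[["theta"]])
  if (vx <= 0 || abs(cos(X0[["theta"]])) > 1e-12)
    stop("solve_time_optimal: target infeasible without actuation")
  Tmin <- (problem$x1 - X0[["x"]]) / vx
  tt <- seq(0, Tmin, length.out = 200)
  ref <- reference_trajectory(X0, tt, params)
  traj <- new_trajectory(data.frame(t = tt, x = ref[, 1], z = ref[, 2],
                                    theta = ref[, 3], u = 0),
                         params)
  structure(list(T_min = Tmin, trajectory = traj,
                 switch_times = numeric(0), durations = Tmin, s0 = 0,
                 problem = problem,
                 diagnostics = list(status = "analytic (no actuation)",
                                    constraint_violation = 0,
                                    seed = "straight line", n_starts = 0,
                                    n_segments = 1, zmin = X0[["z"]])),
            class = "ws_optimal_solution")
}

#' @export
print.ws_optimal_solution <- function(x, ...) {
  cat(sprintf("Minimum-time solution (Problem %d)\n",
              x$problem$problem_id))
  cat(sprintf("  T_min = %.6f with %d control switches (seed: %s)\n",
              x$T_min, length(x$switch_times), x$diagnostics$seed))
  cat(sprintf("  terminal constraint violation %.2e, min height %.3f\n",
              x$diagnostics$constraint_violation, x$diagnostics$zmin))
  invisible(x)
}

#' Extract control switch times from a trajectory
#'
#' Times at which the control trace crosses zero with near-saturated values
#' (\code{|u| >= (1 - tol) u_max}) on both sides.  For solver output the
#' exact switch times stored with the trajectory are returned.
#'
#' @param trajectory a \code{ws_trajectory} with a control column.
#' @param tol saturation tolerance.
#' @param u_max control amplitude; taken from the trajectory parameters if
#'   missing.
#' @return Numeric vector of switch times; attribute \code{mean_spacing}
#'   holds the mean inter-switch interval (with a warning if fewer than two
#'   switches are present).
#' @export
extract_switch_times <- function(trajectory, tol = 0.01, u_max = NULL) {
  sw <- attr(trajectory, "switch_times")
  if (!is.null(sw) && length(sw)) {
    out <- sw
  } else {
    if (is.null(u_max)) u_max <- attr(trajectory, "params")$u_max
    u <- trajectory$u; tt <- trajectory$t
    sat <- abs(u) >= (1 - tol) * u_max
    i <- which(sat[-length(u)] & sat[-1] &
                 sign(u[-length(u)]) * sign(u[-1]) < 0)
    out <- (tt[i] + tt[i + 1]) / 2
  }
  if (length(out) < 2) {
    warning("fewer than two switches; no spacing estimate")
    attr(out, "mean_spacing") <- NA_real_
  } else {
    attr(out, "mean_spacing") <- mean(diff(out))
  }
  out
}

#' Verify a solution's switching pattern against the maximum principle
#'
#' Along a converged minimum-time arc there must exist a nontrivial costate
#' whose switching function changes sign exactly where the control switches.
#' Costate solutions are linear in the terminal condition, so two backward
#' basis integrations span all candidates compatible with the terminal
#' transversality structure (free components have zero costate); the best
#' terminal costate direction is found by a grid scan and the fraction of
#' trajectory samples where \code{sign(h)} matches \code{sign(u)} reported.
#'
#' @param solution a \code{ws_optimal_solution} for Problem 1 (final
#'   \code{theta} free, so \code{ptheta(T) = 0}).
#' @param n_alpha grid size for the terminal costate direction.
#' @return List with \code{agreement} (best fraction in [0,1]) and
#'   \code{alpha} (the best direction).
#' @export
pmp_switching_consistency <- function(solution, n_alpha = 360L) {
  stopifnot(inherits(solution, "ws_optimal_solution"))
  problem <- solution$problem
  if (problem$problem_id != 1)
    stop("implemented for Problem 1 (free terminal orientation)")
  params <- problem$params
  traj <- solution$trajectory
  Tm <- solution$T_min
  n <- nrow(traj)
  iT <- n
  XT <- c(traj$x[iT], traj$z[iT], traj$theta[iT])
  # backward integration of state + two costate basis solutions
  ufun <- stats::approxfun(traj$t, traj$u, method = "constant", rule = 2)
  rhs <- function(t, y, parms) {
    s <- y[1:3]
    u <- ufun(t)
    A <- dynamics_jacobian(s, u, t, params)$A
    ds <- state_derivative(s, u, t, params)
    dp1 <- -as.numeric(t(A) %*% y[4:6])
    dp2 <- -as.numeric(t(A) %*% y[7:9])
    list(c(ds, dp1, dp2))
  }
  y0 <- c(XT, 1, 0, 0, 0, 1, 0)  # ptheta(T) = 0 in both basis vectors
  times <- seq(Tm, 0, length.out = 400)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      rtol = 1e-8, atol = 1e-10)
  tt <- sol[, 1]
  h1 <- h2 <- numeric(length(tt))
  for (i in seq_along(tt)) {
    st <- sol[i, 2:4]
    h1[i] <- switching_function(st, c(sol[i, 5:7], -1), tt[i], params)
    h2[i] <- switching_function(st, c(sol[i, 8:10], -1), tt[i], params)
  }
  us <- ufun(tt)
  ok <- abs(us) > 0.5 * params$u_max
  alphas <- seq(0, 2 * pi, length.out = n_alpha + 1)[-(n_alpha + 1)]
  agree <- vapply(alphas, function(a) {
    h <- cos(a) * h1 + sin(a) * h2
    mean(sign(h[ok]) == sign(us[ok]))
  }, numeric(1))
  ib <- which.max(agree)
  list(agreement = agree[ib], alpha = alphas[ib])
}
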