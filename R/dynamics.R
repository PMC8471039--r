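#' Wall-generated oscillatory flow field
#'
#' Far-field flow induced at height \code{z} by an active wall at \code{z = 0}
#' carrying a metachronal travelling wave of amplitude \code{u}:
#' \deqn{U_x = u e^{-kz} (1 - kz) \sin(kx - \omega t),}
#' \deqn{U_z = -u e^{-kz} kz \cos(kx - \omega t),}
#' \deqn{\Omega_y = \tfrac{1}{2} u e^{-kz} k \sin(kx - \omega t).}
#' The flow organises into counter-rotating cells of width \eqn{\pi/k}; the
#' horizontal component changes sign across \eqn{z = 1/k} and across cell
#' borders \eqn{kx - \omega t = n\pi}.
#'
#' @param x,z evaluation point (vectors recycled to common length); requires
#'   \code{z >= 0}.
#' @param t time.
#' @param u wave amplitude (the control).
#' @param params a \code{\link{model_params}} object (only \code{k} and
#'   \code{omega} are used).
#' @return A list with components \code{Ux}, \code{Uz}, \code{Omega_y}.
#' @examples
#' p <- model_params(omega = 1, u_max = 1)
#' wall_flow(0, 2, 0, 1, p)
#' @export
wall_flow <- function(x, z, t, u, params) {
  if (any(z < 0))
    stop("wall_flow: z must be non-negative (flow defined above the wall)")
  k <- params$k
  ph <- k * x - params$omega * t
  E <- exp(-k * z)
  list(Ux = u * E * (1 - k * z) * sin(ph),
       Uz = -u * E * k * z * cos(ph),
       Omega_y = 0.5 * u * E * k * sin(ph))
}

#' Free-swimming velocity
#'
#' Translational velocity of the swimmer in still fluid,
#' \eqn{(-v\sin\theta,\ v\cos\theta)}; the free angular velocity is
#' identically zero.
#'
#' @param theta orientation angle from the +z axis (radians).
#' @param v swimming speed (>= 0).
#' @return A list with components \code{Ux} and \code{Uz}.
#' @examples
#' free_velocity(-pi / 2, 1) # moving towards +x
#' @export
free_velocity <- function(theta, v) {
  stopifnot(v >= 0)
  list(Ux = -v * sin(theta), Uz = v * cos(theta))
}

#' Far-field squirmer-wall interaction
#'
#' Leading-order effect of the no-slip wall on a squirmer with stresslet
#' parameter \code{B2} at height \code{z}:
#' \deqn{U_x^b = -\frac{3 a^2 B_2}{40 z^2}\sin 2\theta,\quad
#'       U_z^b = \frac{9 a^2 B_2}{16 z^2}\cos 2\theta,\quad
#'       \Omega_y^b = -\frac{3 a^2 B_2}{40 z^3}\sin 2\theta.}
#' For a swimmer heading along the wall (\eqn{\theta = -\pi/2},
#' \eqn{\cos 2\theta = -1}) a puller (\code{B2 > 0}) is attracted to the wall
#' and a pusher (\code{B2 < 0}) repelled, the behaviour the double-angle
#' reading reproduces.  An alternative squared-angle reading
#' (\eqn{\sin^2\theta,\ \cos^2\theta}) is exposed through \code{reading} for
#' comparison; it predicts no vertical effect at \eqn{\theta = -\pi/2} and is
#' not the default.
#'
#' @param z height above the wall (> 0).
#' @param theta orientation angle (radians).
#' @param a swimmer radius.
#' @param B2 squirmer parameter (signed; 0 = neutral, exact zero interaction).
#' @param reading \code{"double"} (default) or \code{"squared"}.
#' @return A list with components \code{Ux}, \code{Uz}, \code{Omega_y}.
#' @examples
#' squirmer_wall_velocity(1, -pi / 2, 1, 16)
#' @export
squirmer_wall_velocity <- function(z, theta, a, B2,
                                   reading = c("double", "squared")) {
  reading <- match.arg(reading)
  if (any(z <= 0))
    stop("squirmer_wall_velocity: z must be positive")
  if (reading == "double") {
    s <- sin(2 * theta); c2 <- cos(2 * theta)
  } else {
    s <- sin(theta)^2; c2 <- cos(theta)^2
  }
  list(Ux = -3 * a^2 * B2 / (40 * z^2) * s,
       Uz = 9 * a^2 * B2 / (16 * z^2) * c2,
       Omega_y = -3 * a^2 * B2 / (40 * z^3) * s)
}

#' Time derivative of the swimmer state
#'
#' Right-hand side of the equations of motion: the componentwise sum of the
#' free-swimming velocity, the wall-generated flow and, if enabled in
#' \code{params}, the far-field squirmer-wall interaction.  The orientation
#' rate has no free-swimming contribution.
#'
#' @param state a \code{\link{swimmer_state}} (or length-3 numeric
#'   \code{c(x, z, theta)}).
#' @param u control amplitude.  Values outside \code{[u_min, u_max]} trigger a
#'   warning but are not rejected.
#' @param t time.
#' @param params a \code{\link{model_params}} object.
#' @return Named numeric vector \code{c(dx, dz, dtheta)}.
#' @examples
#' p <- model_params(omega = 4, u_max = 5)
#' state_derivative(swimmer_state(0, 2, 0), 0, 0, p)
#' @export
state_derivative <- function(state, u, t, params) {
  X <- as_ws_state(state)
  if (u < params$u_min - 1e-12 || u > params$u_max + 1e-12)
    warning("control outside [u_min, u_max]")
  fr <- free_velocity(X[["theta"]], params$v)
  wf <- wall_flow(X[["x"]], X[["z"]], t, u, params)
  d <- c(dx = fr$Ux + wf$Ux, dz = fr$Uz + wf$Uz, dtheta = wf$Omega_y)
  if (isTRUE(params$include_wall_interaction) && params$B2 != 0) {
    sq <- squirmer_wall_velocity(X[["z"]], X[["theta"]], params$a, params$B2,
                                 params$squirmer_reading)
    d <- d + c(sq$Ux, sq$Uz, sq$Omega_y)
  }
  d
}

#' Jacobian of the state derivative
#'
#' Analytic derivatives of the equations of motion with respect to the state
#' (\code{d$A}, a 3x3 matrix) and the control (\code{d$B}, a 3-vector).  Used
#' by the controllability analysis (at \code{u = 0}) and by the adjoint
#' equations of the maximum principle.
#'
#' @inheritParams state_derivative
#' @return List with elements \code{A} (3x3) and \code{B} (length 3).
#' @keywords internal
dynamics_jacobian <- function(state, u, t, params) {
  X <- as_ws_state(state)
  x <- X[["x"]]; z <- X[["z"]]; th <- X[["theta"]]
  k <- params$k; v <- params$v
  ph <- k * x - params$omega * t
  E <- exp(-k * z); s <- sin(ph); cc <- cos(ph)
  A <- matrix(0, 3, 3,
              dimnames = list(c("dx", "dz", "dtheta"), c("x", "z", "theta")))
  A[1, 1] <- u * E * (1 - k * z) * k * cc
  A[1, 2] <- -u * k * E * (2 - k * z) * s
  A[1, 3] <- -v * cos(th)
  A[2, 1] <- u * E * k^2 * z * s
  A[2, 2] <- -u * k * E * (1 - k * z) * cc
  A[2, 3] <- -v * sin(th)
  A[3, 1] <- 0.5 * u * E * k^2 * cc
  A[3, 2] <- -0.5 * u * E * k^2 * s
  if (isTRUE(params$include_wall_interaction) && params$B2 != 0) {
    if (params$squirmer_reading != "double")
      stop("analytic Jacobian implemented for the double-angle reading only")
    a2 <- params$a^2; B2 <- params$B2
    s2 <- sin(2 * th); c2 <- cos(2 * th)
    A[1, 2] <- A[1, 2] + 2 * 3 * a2 * B2 / (40 * z^3) * s2
    A[1, 3] <- A[1, 3] - 2 * 3 * a2 * B2 / (40 * z^2) * c2
    A[2, 2] <- A[2, 2] - 2 * 9 * a2 * B2 / (16 * z^3) * c2
    A[2, 3] <- A[2, 3] - 2 * 9 * a2 * B2 / (16 * z^2) * s2
    A[3, 2] <- A[3, 2] + 3 * 3 * a2 * B2 / (40 * z^4) * s2
    A[3, 3] <- A[3, 3] - 2 * 3 * a2 * B2 / (40 * z^3) * c2
  }
  B <- c(E * (1 - k * z) * s, -E * k * z * cc, 0.5 * E * k * s)
  list(A = A, B = B)
}

# non-validating right-hand side for use inside adaptive integrators, whose
# trial steps may transiently probe slightly past the wall while the crash
# root is being located; the closed-form flow expressions extend smoothly
rhs_unsafe <- function(y, u, t, params) {
  k <- params$k
  v <- params$v
  ph <- k * y[1] - params$omega * t
  E <- exp(-k * min(max(y[2], -0.2 / k), 50 / k))
  d <- c(-v * sin(y[3]) + u * E * (1 - k * y[2]) * sin(ph),
         v * cos(y[3]) - u * E * k * y[2] * cos(ph),
         0.5 * u * E * k * sin(ph))
  if (isTRUE(params$include_wall_interaction) && params$B2 != 0) {
    zz <- max(y[2], 0.02)
    sq <- squirmer_wall_velocity(zz, y[3], params$a, params$B2,
                                 params$squirmer_reading)
    d <- d + c(sq$Ux, sq$Uz, sq$Omega_y)
  }
  d
}

#' Integrate the swimmer equations of motion
#'
#' Adaptive integration of the controlled dynamics on \code{[0, T]}.  The
#' control may be a constant, a function \code{u(t, state)}, or a
#' \code{\link{policy_spec}}; for bang-bang policies the switching surfaces
#' (\code{sin(pi t / T_switch + phase) = 0} for the open-loop policy,
#' \code{sin(kx - omega t) = 0} for the feedback policy) are located by root
#' finding and the integration restarts there, so the discontinuous
#' right-hand side never crosses a step.  Integration stops early, with the
#' trajectory flagged as crashed, if \code{z} falls below the crash threshold.
#'
#' @param params a \code{\link{model_params}} object.
#' @param control constant numeric, function \code{(t, state) -> u}, or a
#'   \code{\link{policy_spec}}.
#' @param X0 initial \code{\link{swimmer_state}}.
#' @param T horizon (> 0).
#' @param n_out number of output samples (approximately uniform in time).
#' @param rtol,atol solver tolerances.
#' @return A \code{ws_trajectory}: a data frame with columns
#'   \code{t, x, z, theta, u} and attributes \code{params}, \code{crashed},
#'   \code{crash_time}.
#' @examples
#' p <- model_params(omega = 4, u_max = 5)
#' tr <- integrate_swimmer(p, 0, swimmer_state(0, 2, 0), 1)
#' tail(tr, 1) # straight free-swimming line
#' @export
integrate_swimmer <- function(params, control, X0, T,
                              n_out = max(200L, ceiling(200 * T)),
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(T > 0)
  X0 <- as_ws_state(X0)
  zc <- params$crash_threshold

  if (inherits(control, "ws_policy")) {
    return(integrate_policy(params, control, X0, T, n_out, rtol, atol))
  }
  ufun <- if (is.function(control)) control else {
    u0 <- control
    function(t, state) u0
  }

  rhs <- function(t, y, parms) {
    u <- ufun(t, y)
    list(rhs_unsafe(y, u, t, params))
  }
  rootf <- function(t, y, parms) y[2] - zc
  times <- seq(0, T, length.out = n_out + 1L)
  sol <- deSolve::lsodar(y = unclass(X0), times = times, func = rhs,
                         parms = NULL, rtol = rtol, atol = atol,
                         rootfunc = rootf)
  tt <- sol[, 1]
  iroot <- attr(sol, "iroot")
  crashed <- !is.null(iroot) && !all(is.na(iroot)) && any(iroot != 0) &&
    abs(tt[length(tt)] - T) > 1e-10
  uu <- vapply(seq_along(tt),
               function(i) ufun(tt[i], sol[i, 2:4]), numeric(1))
  new_trajectory(data.frame(t = tt, x = sol[, 2], z = sol[, 3],
                            theta = sol[, 4], u = uu),
                 params, crashed = isTRUE(crashed),
                 crash_time = if (isTRUE(crashed)) tt[length(tt)] else NA_real_)
}

# event-accurate integration of the bang-bang policies: within a segment the
# control is constant; the switching surface is located by lsodar's root
# finder and integration restarts there with the flipped control value.
integrate_policy <- function(params, spec, X0, T, n_out, rtol, atol) {
  zc <- params$crash_threshold
  k <- params$k; om <- params$omega
  switch_arg <- switch(spec$kind,
    open_loop = function(t, y) sin(pi * t / spec$T_switch + spec$phase),
    feedback = function(t, y) sin(k * y[1] - om * t),
    none = NULL)
  if (spec$kind == "none") {
    return(integrate_swimmer(params, 0, X0, T, n_out, rtol, atol))
  }
  uval <- function(t, y) {
    s <- switch_arg(t, y)
    amp <- if (spec$kind == "feedback") -spec$u_max else spec$u_max
    amp * sign(s)
  }
  rhs <- function(t, y, parms) list(rhs_unsafe(y, parms, t, params))
  out <- NULL
  t0 <- 0; y0 <- unclass(X0)
  crashed <- FALSE; crash_time <- NA_real_
  grid <- seq(0, T, length.out = n_out + 1L)
  n_seg <- 0L
  while (t0 < T - 1e-12) {
    n_seg <- n_seg + 1L
    if (n_seg > 2000L) {
      warning("integrate_swimmer: more than 2000 policy segments; stopping")
      break
    }
    u0 <- uval(t0 + 1e-10, y0)
    rootf <- function(t, y, parms) c(switch_arg(t, y), y[2] - zc)
    times <- unique(c(t0, grid[grid > t0 + 1e-12], T))
    seg <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = u0,
                           rtol = rtol, atol = atol, rootfunc = rootf)
    tt <- seg[, 1]
    useg <- rep(u0, length(tt))
    out <- rbind(out, cbind(seg, u = useg))
    tend <- tt[length(tt)]
    iroot <- attr(seg, "iroot")  # indicator vector over the root functions
    if (!is.null(iroot) && !all(is.na(iroot)) &&
        length(iroot) >= 2 && iroot[2] != 0) {
      crashed <- TRUE; crash_time <- tend
      break
    }
    if (tend >= T - 1e-12) break
    y0 <- as.numeric(seg[nrow(seg), 2:4])
    # restart just past the located switch, forcing progress if the root
    # finder keeps returning (numerically) the same time
    t0 <- if (tend - t0 < 1e-9) tend + 1e-6 else tend + 1e-9
  }
  df <- data.frame(t = out[, 1], x = out[, 2], z = out[, 3],
                   theta = out[, 4], u = out[, 5])
  df <- df[!duplicated(df$t), ]
  new_trajectory(df, params, crashed = crashed, crash_time = crash_time)
}

new_trajectory <- function(df, params, crashed = FALSE, crash_time = NA_real_,
                           switch_times = numeric(0)) {
  stopifnot(all(c("t", "x", "z", "theta", "u") == names(df)))
  structure(df, class = c("ws_trajectory", "data.frame"), params = params,
            crashed = crashed, crash_time = crash_time,
            switch_times = switch_times)
}

#' @export
print.ws_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Swimmer trajectory: %d samples on [%g, %g]%s\n", n, x$t[1],
              x$t[n], if (isTRUE(attr(x, "crashed"))) "  [CRASHED]" else ""))
  cat(sprintf("  final state: x = %.4f, z = %.4f, theta = %.4f\n",
              x$x[n], x$z[n], x$theta[n]))
  invisible(x)
}

#' Closed-form free-swimming reference trajectory
#'
#' With zero control (and no wall interaction) the swimmer moves along the
#' straight line \eqn{X_{ref}(t) = (x_0 - v t \sin\theta_0,\
#' z_0 + v t \cos\theta_0,\ \theta_0)}.
#'
#' @param X0 initial state.
#' @param t time (vectorised).
#' @param params a \code{\link{model_params}} object (only \code{v} is used).
#' @return Matrix with columns \code{x, z, theta}.
#' @export
reference_trajectory <- function(X0, t, params) {
  X0 <- as_ws_state(X0)
  cbind(x = X0[["x"]] - params$v * t * sin(X0[["theta"]]),
        z = X0[["z"]] + params$v * t * cos(X0[["theta"]]),
        theta = rep(X0[["theta"]], length(t)))
}
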