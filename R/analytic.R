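#' Characteristic parallel flow speed
#'
#' Amplitude of the horizontal wall flow felt by a swimmer holding height
#' \code{z0} under maximal actuation:
#' \eqn{V_0 = u_{max} e^{-k z_0} (1 - k z_0)} (signed; negative above the
#' cell-reversal height \eqn{z_0 = 1/k}).
#'
#' @param z0 wall distance (>= 0).
#' @param u_max control amplitude.
#' @param k wall wave number.
#' @return Signed characteristic speed.
#' @examples
#' characteristic_speed(2, 1, 1) # -exp(-2)
#' @export
characteristic_speed <- function(z0, u_max, k) {
  stopifnot(all(z0 >= 0))
  u_max * exp(-k * z0) * (1 - k * z0)
}

#' Wall distance maximising the characteristic speed
#'
#' Over the outer region \eqn{z_0 > 1/k} the magnitude
#' \eqn{|V_0(z_0)| = u_{max} e^{-k z_0} (k z_0 - 1)} is unimodal with maximum
#' \eqn{u_{max} e^{-2}} at \eqn{z_0 = 2/k}, which minimises the estimated
#' transit time for wall-parallel transport.
#'
#' @param k wall wave number (> 0).
#' @return The optimal distance \code{2 / k}.
#' @examples
#' optimal_distance(1)
#' @export
optimal_distance <- function(k) {
  stopifnot(k > 0)
  2 / k
}

#' Average flow gain of the synchronised bang-bang strategy
#'
#' Mean horizontal velocity gained from the wall flow by a swimmer that flips
#' the wave amplitude every time it crosses a flow-cell border, at the lowest
#' order in \eqn{V_0/\omega}:
#' \deqn{v_{flow} = \frac{2 V_0}{\pi}\left[1 - \frac{k}{\omega}\left(v
#'   \sin\theta_0 + \frac{2 V_0}{\pi}\right)\right],}
#' the first-order solution of the self-consistency relation
#' \eqn{v_{flow} = \Delta x / T_{switch}} with per-cell displacement
#' \eqn{\Delta x = 2 V_0 / \omega}.  Here \eqn{V_0} enters as a magnitude:
#' the transport direction is set by the swimmer's heading.
#'
#' @param z0 wall distance of the (frozen) reference height.
#' @param theta0 orientation angle; the estimate assumes near-wall-parallel
#'   heading (\eqn{\theta_0} close to \eqn{-\pi/2}).
#' @param params a \code{\link{model_params}} object.
#' @return Estimated average flow gain (velocity, >= 0 in the transport
#'   regime).
#' @export
flow_gain <- function(z0, theta0, params) {
  k <- params$k; om <- params$omega; v <- params$v
  if (om / k <= 2 * v)
    warning("flow_gain: wave speed omega/k is not large compared with the ",
            "swimming speed; the lowest-order estimate degrades")
  V0 <- abs(characteristic_speed(z0, params$u_max, k))
  (2 * V0 / pi) * (1 - (k / om) * (v * sin(theta0) + 2 * V0 / pi))
}

#' Time between optimal control switches
#'
#' The synchronised strategy switches every time the swimmer crosses a
#' flow-cell border, i.e. each half-period of the phase
#' \eqn{k x(t) - \omega t} seen by the swimmer.  With horizontal transport
#' speed \eqn{v_h + v_{flow}} (where \eqn{v_h = -v\sin\theta_0} is the free
#' horizontal speed) the crossing period is
#' \deqn{T_{switch} = \frac{\pi}{\omega - k(v_h + v_{flow})}.}
#' Its inverse is affine in \eqn{\omega} with slope \eqn{1/\pi}.
#'
#' @inheritParams flow_gain
#' @param v_flow optional flow gain; computed via \code{\link{flow_gain}} if
#'   missing.
#' @return Estimated switch period (time).
#' @export
switch_time <- function(z0, theta0, params, v_flow = NULL) {
  if (is.null(v_flow)) v_flow <- flow_gain(z0, theta0, params)
  vh <- -params$v * sin(theta0)
  den <- params$omega - params$k * (vh + v_flow)
  if (den <= 0)
    stop("switch_time: wave is not faster than the swimmer ",
         "(non-positive comoving frequency); no synchronised switching regime")
  pi / den
}

#' Estimated minimal transit time for wall-parallel transport
#'
#' \deqn{T_{min} = \frac{x_1 - x_0}{v + v_{flow}}:}
#' the target distance divided by the boosted effective speed.  Minimal over
#' \code{z0} at \code{z0 = 2/k}, where \eqn{|V_0|} is maximal.
#'
#' @param x0,x1 start and target horizontal positions (\code{x1 > x0}).
#' @inheritParams flow_gain
#' @return Estimated minimal time.
#' @export
min_time_estimate <- function(x0, x1, z0, theta0, params) {
  stopifnot(x1 > x0)
  (x1 - x0) / (params$v + flow_gain(z0, theta0, params))
}

#' Leading-order velocity boost at the optimal wall distance
#'
#' At \eqn{z_0 = 2/k} the characteristic speed is \eqn{u_{max} e^{-2}} and the
#' leading-order relative gain in transport speed is
#' \deqn{b = \frac{v_{flow}}{v} = \frac{2 e^{-2}}{\pi}\,
#'   \frac{u_{max}}{v},}
#' about 8.6\% of the free speed when \eqn{u_{max} = v} and five times that
#' when \eqn{u_{max} = 5v}.
#'
#' @param u_max control amplitude.
#' @param v swimming speed (> 0).
#' @return Dimensionless boost \eqn{v_{flow}/v}.
#' @examples
#' boost(1, 1)
#' boost(5, 1)
#' @export
boost <- function(u_max, v) {
  if (v <= 0)
    stop("boost: requires v > 0 (a passive particle gains no relative boost)")
  2 * exp(-2) / pi * u_max / v
}

#' Horizontal motion under constant control at frozen height and heading
#'
#' Exact solution of the frozen-state horizontal dynamics
#' \deqn{\dot x = -v \sin\theta_0 + V_0 \sin(k x - \omega t)}
#' with constant control (so \eqn{V_0 =
#' u_{max} e^{-k z_0}(1 - k z_0)}, signed), used to derive the per-cell
#' displacement and the flow-gain estimate.  In terms of the phase
#' \eqn{y = k x - \omega t} the equation is autonomous with comoving
#' frequency \eqn{\omega_c = \omega + k v \sin\theta_0}, and
#' \deqn{x(t) = \frac{1}{k}\left[\omega t + 2\arctan\!\left(
#'   \frac{k V_0 - \omega_0 \tan(\omega_0 (t - T_0)/2)}{\omega_c}\right)
#'   \right],\qquad \omega_0 = \sqrt{\omega_c^2 - k^2 V_0^2},}
#' where \eqn{T_0} fixes the phase at which the tangent argument vanishes and
#' the arctan-tan composition is unwrapped across half-periods so that
#' \eqn{x(t)} is continuous.  The leading-order displacement contributed by
#' the flow between two successive cell-border crossings is
#' \eqn{\Delta x = 2 V_0 / \omega}.
#'
#' @param t time (vectorised).
#' @param T0 phase reference time (integration constant of the closed form).
#' @param theta0 frozen orientation.
#' @param z0 frozen height.
#' @param params a \code{\link{model_params}} object; the control is held at
#'   \code{u_max}.
#' @return Numeric vector \code{x(t)} with \code{x} chosen so that the phase
#'   \eqn{y(T_0) = 2\arctan(k V_0/\omega_c)}.
#' @export
constant_control_x <- function(t, T0, theta0, z0, params) {
  k <- params$k; om <- params$omega; v <- params$v
  V0 <- characteristic_speed(z0, params$u_max, k)
  omc <- om + k * v * sin(theta0)
  w0sq <- omc^2 - k^2 * V0^2
  if (w0sq <= 0)
    stop("constant_control_x: |k V0| >= |omega_c|; the swimmer can lock to ",
         "the wave and the oscillatory closed form does not apply")
  w0 <- sqrt(w0sq)
  # unwrap arctan(tan(.)) across half-periods of the inner angle
  ang <- w0 * (t - T0) / 2
  n <- floor((ang + pi / 2) / pi)
  y <- 2 * (atan((k * V0 - w0 * tan(ang)) / omc) - pi * n)
  (y + om * t) / k
}

#' Closed-form transport estimates for a scenario
#'
#' Convenience wrapper collecting the characteristic speed, flow gain, switch
#' period, minimal-time estimate and boost for a wall-parallel transport
#' scenario.
#'
#' @param x0,x1 start and target horizontal positions.
#' @param z0 wall distance.
#' @param theta0 initial orientation.
#' @param params a \code{\link{model_params}} object.
#' @return A \code{ws_estimate} list with fields \code{V0}, \code{v_flow},
#'   \code{T_switch}, \code{T_min}, \code{boost}.
#' @export
transport_estimate <- function(x0, x1, z0, theta0, params) {
  V0 <- characteristic_speed(z0, params$u_max, params$k)
  vf <- flow_gain(z0, theta0, params)
  structure(list(V0 = V0, v_flow = vf,
                 T_switch = switch_time(z0, theta0, params, v_flow = vf),
                 T_min = min_time_estimate(x0, x1, z0, theta0, params),
                 boost = vf / params$v),
            class = "ws_estimate")
}

#' @export
print.ws_estimate <- function(x, ...) {
  cat("Wall-parallel transport estimates\n")
  cat(sprintf("  V0 = %.4f, v_flow = %.4f (boost %.1f%%)\n",
              x$V0, x$v_flow, 100 * x$boost))
  cat(sprintf("  T_switch = %.4f, T_min = %.4f\n", x$T_switch, x$T_min))
  invisible(x)
}

#' Back-solve the wall distance realising a given characteristic speed
#'
#' Finds \code{z0} with \eqn{|V_0(z_0)| = } \code{V0_target} for the given
#' amplitude, on the outer branch \eqn{z_0 > 1/k} where the flow opposes the
#' wave.  Two such heights exist (on either side of the maximiser
#' \eqn{2/k}); \code{branch} selects the farther (default, safer from the
#' wall) or nearer one.
#'
#' @param V0_target target magnitude (0 < V0_target < u_max e^{-2}).
#' @param u_max control amplitude.
#' @param k wall wave number.
#' @param branch \code{"far"} (root above \code{2/k}) or \code{"near"}.
#' @return Height \code{z0}.
#' @export
distance_for_speed <- function(V0_target, u_max, k, branch = c("far", "near")) {
  branch <- match.arg(branch)
  stopifnot(V0_target > 0, V0_target < u_max * exp(-2) - 1e-12)
  f <- function(z) abs(characteristic_speed(z, u_max, k)) - V0_target
  iv <- if (branch == "far") c(2 / k, 50 / k) else c(1 / k + 1e-9, 2 / k)
  stats::uniroot(f, iv, tol = 1e-12)$root
}
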