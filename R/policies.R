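#' Driving policy specification
#'
#' @param kind \code{"open_loop"} (periodic bang-bang in time),
#'   \code{"feedback"} (bang-bang synchronised with the flow cell containing
#'   the swimmer) or \code{"none"} (zero control).
#' @param u_max control amplitude.
#' @param T_switch switch half-period (open loop only, > 0).
#' @param phase phase offset of the open-loop square wave (radians).
#' @return A \code{ws_policy} list.
#' @export
policy_spec <- function(kind = c("open_loop", "feedback", "none"),
                        u_max = NULL, T_switch = NULL, phase = 0) {
  kind <- match.arg(kind)
  if (kind == "open_loop") {
    stopifnot(!is.null(T_switch), T_switch > 0)
  }
  if (kind != "none") stopifnot(!is.null(u_max), u_max >= 0)
  structure(list(kind = kind, u_max = u_max, T_switch = T_switch,
                 phase = phase),
            class = "ws_policy")
}

#' Open-loop periodic bang-bang control
#'
#' \eqn{u(t) = u_{max}\, \mathrm{sgn}\, \sin(\pi t / T_{switch} + \phi)}:
#' a fixed square wave mimicking the optimal switching cadence with no
#' knowledge of the swimmer state.  \code{sgn(0) = 0} by convention.
#'
#' @param t time (vectorised).
#' @param spec an open-loop \code{\link{policy_spec}}.
#' @return Control value(s).
#' @export
open_loop_control <- function(t, spec) {
  stopifnot(spec$kind == "open_loop")
  spec$u_max * sign(sin(pi * t / spec$T_switch + spec$phase))
}

#' Feedback (closed-loop) synchronised control
#'
#' \eqn{u(t, X) = -u_{max}\, \mathrm{sgn}\, \sin(k x - \omega t)}: switches
#' every time the swimmer crosses a flow-cell border, which requires measuring
#' only the horizontal position.  The leading minus makes the horizontal flow
#' push a swimmer above the cell-reversal height \eqn{z = 1/k} forward.
#'
#' @param t time.
#' @param state \code{\link{swimmer_state}} (only \code{x} is used).
#' @param spec a feedback \code{\link{policy_spec}}.
#' @param params a \code{\link{model_params}} object.
#' @return Control value.
#' @export
feedback_control <- function(t, state, spec, params) {
  stopifnot(spec$kind == "feedback")
  X <- as_ws_state(state)
  -spec$u_max * sign(sin(params$k * X[["x"]] - params$omega * t))
}

#' Run a driving-policy experiment
#'
#' Integrates the closed loop with event-accurate switching and summarises
#' transport performance.
#'
#' @param X0 initial state.
#' @param T horizon.
#' @param spec a \code{\link{policy_spec}}.
#' @param params a \code{\link{model_params}} object.
#' @param ... passed to \code{\link{integrate_swimmer}}.
#' @return List with \code{trajectory} (a \code{ws_trajectory}) and
#'   \code{metrics}, a \code{ws_metrics} list with fields
#'   \code{mean_horizontal_speed}, \code{boost_vs_free},
#'   \code{min_wall_distance}, \code{crashed}, \code{net_rotation}.
#'   \code{boost_vs_free} is the mean horizontal speed relative to the free
#'   speed \code{v}, meaningful for wall-parallel launches
#'   (\eqn{\theta_0 = -\pi/2}).
#' @export
run_policy_experiment <- function(X0, T, spec, params, ...) {
  X0 <- as_ws_state(X0)
  traj <- integrate_swimmer(params, spec, X0, T, ...)
  n <- nrow(traj)
  elapsed <- traj$t[n] - traj$t[1]
  mhs <- (traj$x[n] - traj$x[1]) / elapsed
  metrics <- structure(
    list(mean_horizontal_speed = mhs,
         boost_vs_free = mhs / params$v - 1,
         min_wall_distance = min(traj$z),
         crashed = isTRUE(attr(traj, "crashed")),
         net_rotation = traj$theta[n] - traj$theta[1],
         elapsed = elapsed),
    class = "ws_metrics")
  list(trajectory = traj, metrics = metrics)
}

#' @export
print.ws_metrics <- function(x, ...) {
  cat(sprintf("mean horizontal speed %.4f (boost %.1f%%)%s\n",
              x$mean_horizontal_speed, 100 * x$boost_vs_free,
              if (x$crashed) "  [CRASHED]" else ""))
  cat(sprintf("min wall distance %.4f, net rotation %.4f rad over T = %g\n",
              x$min_wall_distance, x$net_rotation, x$elapsed))
  invisible(x)
}

#' Compare driving policies on a scenario
#'
#' Runs the no-control, open-loop and feedback policies on a common scenario
#' and, for the open loop, sweeps a relative error on the switch period to
#' probe the sensitivity to desynchronisation.  The open-loop period defaults
#' to the analytic estimate \code{\link{switch_time}} evaluated at the initial
#' height, perturbed by each sweep value.
#'
#' @param X0 initial state.
#' @param T horizon.
#' @param params a \code{\link{model_params}} object.
#' @param u_max policy amplitude (defaults to \code{params$u_max}).
#' @param period_errors numeric vector of relative open-loop period errors
#'   (0 = use the estimate as is).
#' @param T_switch optional explicit base period overriding the estimate.
#' @param phase open-loop phase offset.
#' @return Data frame with one row per run: policy, period error, applied
#'   period, and the transport metrics.
#' @export
compare_policies <- function(X0, T, params, u_max = params$u_max,
                             period_errors = 0, T_switch = NULL, phase = 0) {
  X0 <- as_ws_state(X0)
  Ts0 <- if (is.null(T_switch))
    switch_time(X0[["z"]], X0[["theta"]], params) else T_switch
  rows <- list()
  add <- function(policy, perr, Ts, m) {
    rows[[length(rows) + 1]] <<- data.frame(
      policy = policy, period_error = perr,
      T_switch = if (is.null(Ts)) NA_real_ else Ts,
      mean_horizontal_speed = m$mean_horizontal_speed,
      boost_vs_free = m$boost_vs_free,
      min_wall_distance = m$min_wall_distance,
      crashed = m$crashed, net_rotation = m$net_rotation)
  }
  m <- run_policy_experiment(X0, T, policy_spec("none"), params)$metrics
  add("none", NA_real_, NULL, m)
  for (pe in period_errors) {
    Ts <- Ts0 * (1 + pe)
    sp <- policy_spec("open_loop", u_max = u_max, T_switch = Ts,
                      phase = phase)
    m <- run_policy_experiment(X0, T, sp, params)$metrics
    add("open_loop", pe, Ts, m)
  }
  m <- run_policy_experiment(X0, T, policy_spec("feedback", u_max = u_max),
                             params)$metrics
  add("feedback", NA_real_, NULL, m)
  do.call(rbind, rows)
}
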