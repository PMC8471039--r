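#' Model parameters for the wall-driven swimmer
#'
#' Collects the physical parameters of a spherical swimmer moving above an
#' active wall that generates a travelling-wave flow of controllable
#' amplitude.  The default units are the standard nondimensionalisation
#' \code{k = v = 1}, in which \code{omega}, times and speeds are the ratios
#' \eqn{\omega/kv}, \eqn{t k v} and \eqn{u/v}.
#'
#' @param v free swimming speed (length/time, >= 0).
#' @param k wall wave number (1/length, > 0 unless deliberately degenerate).
#' @param omega wall wave angular frequency (1/time).
#' @param u_max upper control amplitude bound (velocity, >= 0).
#' @param u_min lower control amplitude bound; defaults to \code{-u_max}.
#' @param a swimmer radius (length).  Only enters through the squirmer-wall
#'   interaction and the crash threshold.
#' @param B2 squirmer stresslet parameter; \code{B2 > 0} is a puller,
#'   \code{B2 < 0} a pusher, \code{B2 = 0} a neutral swimmer.
#' @param include_wall_interaction logical; add the far-field squirmer-wall
#'   interaction to the equations of motion.
#' @param crash_threshold height below which the swimmer is flagged as having
#'   crashed into the wall.  Defaults to \code{a} when the wall interaction is
#'   enabled and to \code{0.05/k} in point-swimmer mode.
#' @param squirmer_reading trigonometric reading of the squirmer-wall
#'   interaction: \code{"double"} uses \eqn{\sin 2\theta,\ \cos 2\theta}
#'   (default), \code{"squared"} uses \eqn{\sin^2\theta,\ \cos^2\theta}.
#'
#' @return An object of class \code{ws_params} (a named list).
#' @examples
#' p <- model_params(omega = 4, u_max = 5)
#' p$u_min
#' @export
model_params <- function(v = 1, k = 1, omega, u_max, u_min = -u_max,
                         a = 0.3, B2 = 0, include_wall_interaction = FALSE,
                         crash_threshold = NULL,
                         squirmer_reading = c("double", "squared")) {
  squirmer_reading <- match.arg(squirmer_reading)
  stopifnot(is.numeric(v), length(v) == 1L, v >= 0,
            is.numeric(k), length(k) == 1L,
            is.numeric(omega), length(omega) == 1L,
            is.numeric(u_max), length(u_max) == 1L,
            is.numeric(u_min), length(u_min) == 1L,
            is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(B2), length(B2) == 1L,
            is.logical(include_wall_interaction))
  if (u_min > u_max)
    stop("u_min must not exceed u_max")
  if (is.null(crash_threshold)) {
    crash_threshold <- if (include_wall_interaction) a else 0.05 / max(k, .Machine$double.eps)
  }
  structure(list(v = v, k = k, omega = omega, u_max = u_max, u_min = u_min,
                 a = a, B2 = B2,
                 include_wall_interaction = include_wall_interaction,
                 crash_threshold = crash_threshold,
                 squirmer_reading = squirmer_reading),
            class = "ws_params")
}

#' @export
print.ws_params <- function(x, ...) {
  cat("Wall-driven swimmer parameters\n")
  cat(sprintf("  v = %g, k = %g, omega = %g\n", x$v, x$k, x$omega))
  cat(sprintf("  control bounds [%g, %g]\n", x$u_min, x$u_max))
  if (x$include_wall_interaction)
    cat(sprintf("  squirmer-wall interaction ON: a = %g, B2 = %g (%s reading)\n",
                x$a, x$B2, x$squirmer_reading))
  cat(sprintf("  crash threshold z <= %g\n", x$crash_threshold))
  invisible(x)
}

#' Swimmer state
#'
#' Position and orientation of the swimmer in the laboratory frame.  The wall
#' lies at \code{z = 0}; \code{theta} is the angle between the swimming
#' direction and the +z axis, so the free velocity is
#' \eqn{(-v\sin\theta,\ v\cos\theta)} and \eqn{\theta = -\pi/2} points along
#' +x.  \code{theta} is stored unwrapped so net rotation is measurable.
#'
#' @param x horizontal position.
#' @param z height above the wall (must be > 0 for a physically valid state).
#' @param theta orientation angle from the +z axis (radians, unwrapped).
#' @return An object of class \code{ws_state}, a named numeric vector.
#' @examples
#' swimmer_state(0, 3, -pi / 2)
#' @export
swimmer_state <- function(x, z, theta) {
  stopifnot(is.numeric(x), is.numeric(z), is.numeric(theta),
            length(x) == 1L, length(z) == 1L, length(theta) == 1L,
            is.finite(x), is.finite(z), is.finite(theta))
  structure(c(x = unname(x), z = unname(z), theta = unname(theta)),
            class = "ws_state")
}

as_ws_state <- function(X) {
  if (inherits(X, "ws_state")) return(X)
  X <- unlist(X, use.names = FALSE)
  stopifnot(length(X) == 3L)
  swimmer_state(X[1], X[2], X[3])
}

# parameter vector handed to the compiled kernels
par_vec <- function(params) {
  c(params$v, params$k, params$omega, params$B2, params$a,
    as.numeric(isTRUE(params$include_wall_interaction)))
}
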