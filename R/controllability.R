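#' Linearisation around a free-swimming reference trajectory
#'
#' Linearises the controlled dynamics about the straight free trajectory
#' \code{Xref(t)} (reference control \eqn{u_{ref} = 0}), giving the
#' time-varying linear system \eqn{\dot X = A(t) X + B(t) u}.  \code{A(t)} is
#' the state Jacobian of the dynamics at \code{(Xref(t), 0)} -- only the
#' orientation column is nonzero, since at zero amplitude the flow vanishes --
#' and \code{B(t)} is the wall-flow response per unit amplitude evaluated
#' along the reference.
#'
#' The analysis is for the flow-driven dynamics alone; it refuses parameter
#' sets with the squirmer-wall interaction enabled.
#'
#' @param params a \code{\link{model_params}} object with
#'   \code{include_wall_interaction = FALSE}.
#' @param X0 initial state of the reference trajectory.
#' @param t time (scalar).
#' @return List with \code{A} (3x3 matrix), \code{B} (length-3 vector) and
#'   \code{Xref} (the reference state at \code{t}).
#' @export
linearize <- function(params, X0, t) {
  check_no_interaction(params, "linearize")
  Xr <- reference_trajectory(X0, t, params)
  st <- swimmer_state(Xr[1, "x"], Xr[1, "z"], Xr[1, "theta"])
  J <- dynamics_jacobian(st, 0, t, params)
  list(A = J$A, B = J$B, Xref = st)
}

check_no_interaction <- function(params, who) {
  if (isTRUE(params$include_wall_interaction))
    stop(who, ": the local controllability analysis applies to the ",
         "flow-only dynamics; disable the squirmer-wall interaction and use ",
         "simulation-based checks for the interacting system")
  invisible(TRUE)
}

# --- analytic Kalman blocks ------------------------------------------------
#
# Along the reference, every column of [B | B1 | B2] has the form
#   E(t) * (P(t) sin(phi) + Q(t) cos(phi)),     componentwise,
# with E = exp(-k z(t)), z(t) = z0 + v t cos(theta0),
# phi(t) = k x0 - nu t, nu = omega + k v sin(theta0), and P, Q polynomials in
# t of degree <= 2.  The recursion B_{j+1} = d(B_j)/dt - A B_j acts linearly
# on the (P, Q) coefficients:
#   d/dt [P sin + Q cos] = (P' + nu Q) sin + (Q' - nu P) cos,
# and the common factor E contributes -k v cos(theta0) times the identity.
# Representing each column as two 3x3 coefficient matrices (rows = state
# components, columns = powers of t) keeps the computation exact.

kb_column_step <- function(P, Q, nu, kvc, vc, vs) {
  polyder <- function(M) cbind(M[, 2], 2 * M[, 3], 0)
  Pd <- polyder(P); Qd <- polyder(Q)
  # A acts only through the theta column: (A y)_1 = -v c * y_3,
  # (A y)_2 = -v s * y_3, (A y)_3 = 0
  AP <- rbind(-vc * P[3, ], -vs * P[3, ], 0)
  AQ <- rbind(-vc * Q[3, ], -vs * Q[3, ], 0)
  list(P = Pd + nu * Q - kvc * P - AP,
       Q = Qd - nu * P - kvc * Q - AQ)
}

kb_eval <- function(col, tt, E, sph, cph) {
  tv <- c(1, tt, tt^2)
  E * (as.numeric(col$P %*% tv) * sph + as.numeric(col$Q %*% tv) * cph)
}

#' Kalman-type controllability blocks
#'
#' Builds the 3x3 matrix \eqn{[B(t)\,|\,B_1(t)\,|\,B_2(t)]} with
#' \eqn{B_1 = \dot B - A B} and \eqn{B_2 = \dot B_1 - A B_1}, using exact
#' analytic time derivatives along the free reference trajectory.  The
#' time-varying linear system is controllable on \code{[0, T]} iff this
#' matrix is invertible at some time in the interval.
#'
#' @inheritParams linearize
#' @return 3x3 numeric matrix.
#' @export
kalman_blocks <- function(params, X0, t) {
  check_no_interaction(params, "kalman_blocks")
  X0 <- as_ws_state(X0)
  k <- params$k; v <- params$v; om <- params$omega
  th0 <- X0[["theta"]]; x0 <- X0[["x"]]; z0 <- X0[["z"]]
  s0 <- sin(th0); c0 <- cos(th0)
  nu <- om + k * v * s0
  kvc <- k * v * c0

  # B(t) = E * (P sin(phi) + Q cos(phi)); z(t) = z0 + v c0 t enters (1 - kz)
  # and kz as degree-1 polynomials in t
  P0 <- rbind(c(1 - k * z0, -k * v * c0, 0),  # (1 - k z(t))
              c(0, 0, 0),
              c(k / 2, 0, 0))
  Q0 <- rbind(c(0, 0, 0),
              c(-k * z0, -k * v * c0, 0),      # -k z(t)
              c(0, 0, 0))
  b0 <- list(P = P0, Q = Q0)
  b1 <- kb_column_step(b0$P, b0$Q, nu, kvc, v * c0, v * s0)
  b2 <- kb_column_step(b1$P, b1$Q, nu, kvc, v * c0, v * s0)

  zt <- z0 + v * c0 * t
  ph <- k * x0 - nu * t
  E <- exp(-k * zt); sph <- sin(ph); cph <- cos(ph)
  cbind(B = kb_eval(b0, t, E, sph, cph),
        B1 = kb_eval(b1, t, E, sph, cph),
        B2 = kb_eval(b2, t, E, sph, cph))
}

#' Closed-form controllability determinant
#'
#' Determinant of \code{\link{kalman_blocks}} in closed form:
#' \deqn{\Delta(t) = \tfrac{1}{2} e^{-3 k z(t)}\, k^3 v\, \omega_c
#'   \cos\theta_0 \left[\omega_c\, z(t) \cos\varphi(t) +
#'   v \cos\theta_0 \sin\varphi(t)\right],}
#' with \eqn{z(t) = z_0 + v t \cos\theta_0}, the comoving frequency
#' \eqn{\omega_c = \omega + k v \sin\theta_0} (the wave frequency seen by the
#' translating swimmer, which vanishes when the horizontal swimming speed
#' equals the wave speed) and \eqn{\varphi(t) = k x_0 - \omega_c t}.
#' \eqn{\Delta} vanishes identically iff one of \eqn{k}, \eqn{v},
#' \eqn{\omega_c}, \eqn{\cos\theta_0} is zero; otherwise its zeros are
#' isolated and the system is locally controllable around the reference.
#'
#' @inheritParams linearize
#' @param t time (vectorised).
#' @return Numeric vector of determinant values.
#' @export
controllability_determinant <- function(params, X0, t) {
  check_no_interaction(params, "controllability_determinant")
  X0 <- as_ws_state(X0)
  k <- params$k; v <- params$v; om <- params$omega
  th0 <- X0[["theta"]]; x0 <- X0[["x"]]; z0 <- X0[["z"]]
  s0 <- sin(th0); c0 <- cos(th0)
  nu <- om + k * v * s0
  zt <- z0 + v * c0 * t
  ph <- k * x0 - nu * t
  0.5 * exp(-3 * k * zt) * k^3 * v * nu * c0 *
    (nu * zt * cos(ph) + v * c0 * sin(ph))
}

#' Classify structural controllability degeneracies
#'
#' Checks the four parameter configurations under which the controllability
#' determinant vanishes identically and local linear controllability fails:
#' \describe{
#'   \item{\code{k_zero}}{no spatial wave structure: a uniformly sliding wall
#'     cannot rotate the swimmer (trivially uncontrollable).}
#'   \item{\code{v_zero}}{passive particle: it can only follow a single flow
#'     line (trivially uncontrollable).}
#'   \item{\code{omega_c_zero}}{the comoving frequency
#'     \eqn{\omega + k v \sin\theta_0} vanishes: the swimmer translates with
#'     the wave front and sees a frozen flow.}
#'   \item{\code{theta0_parallel_zero}}{\eqn{\cos\theta_0 = 0}, wall-parallel
#'     initial orientation: along a height-constant reference the horizontal
#'     and rotational flow responses are proportional, so the linearisation
#'     cannot separate them.  (First-order analysis only; the nonlinear
#'     system may still be steerable through height excursions.)}
#' }
#'
#' @inheritParams linearize
#' @param T horizon over which the determinant is sampled.
#' @param n_grid number of grid times.
#' @param tol absolute tolerance for flagging a parameter as zero.
#' @return A \code{ws_controllability} report: list with \code{determinant}
#'   (sampled on the grid), \code{times}, \code{controllable},
#'   \code{degeneracies} (character vector of flags) and \code{omega_c}.
#' @export
classify_degeneracies <- function(params, X0, T = 5, n_grid = 1000L,
                                  tol = 1e-12) {
  X0 <- as_ws_state(X0)
  th0 <- X0[["theta"]]
  omega_c <- params$omega + params$k * params$v * sin(th0)
  flags <- c(k_zero = abs(params$k) <= tol,
             v_zero = abs(params$v) <= tol,
             omega_c_zero = abs(omega_c) <= tol,
             theta0_parallel_zero = abs(cos(th0)) <= tol)
  tt <- seq(0, T, length.out = n_grid)
  dd <- if (isTRUE(params$include_wall_interaction)) {
    rep(NA_real_, n_grid)
  } else {
    controllability_determinant(params, X0, tt)
  }
  scale <- max(abs(dd), na.rm = TRUE)
  nonzero <- is.finite(scale) && scale > 0 &&
    any(abs(dd) > 1e-12 * scale, na.rm = TRUE)
  structure(list(times = tt, determinant = dd,
                 controllable = !any(flags) && nonzero,
                 degeneracies = names(flags)[flags],
                 omega_c = omega_c),
            class = "ws_controllability")
}

#' @export
print.ws_controllability <- function(x, ...) {
  cat("Local controllability around the free reference trajectory\n")
  cat(sprintf("  comoving frequency omega_c = %g\n", x$omega_c))
  if (length(x$degeneracies))
    cat("  structural degeneracies:", paste(x$degeneracies, collapse = ", "),
        "\n")
  cat(sprintf("  verdict: %s\n",
              if (x$controllable) "locally controllable" else
                "NOT controllable (linearised test)"))
  invisible(x)
}
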