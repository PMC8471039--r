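ALLOWED_TOP <- c("name", "params", "state0", "horizon", "policy", "problem",
                 "notes")
ALLOWED_PAR <- c("v", "k", "omega", "u_max", "u_min", "a", "B2",
                 "include_wall_interaction", "crash_threshold",
                 "squirmer_reading")
ALLOWED_POL <- c("kind", "u_max", "T_switch", "phase")
ALLOWED_PRB <- c("id", "x1", "theta1", "z1")

#' Load a scenario configuration
#'
#' Reads a YAML (or JSON) scenario file describing the model parameters,
#' initial state and either a driving policy with a horizon or a minimum-time
#' problem.  Defaults \code{k = v = 1} and \code{u_min = -u_max} are applied;
#' unknown keys are rejected with an error naming the offending field.
#'
#' @param path path to a scenario file.
#' @return A \code{ws_scenario} list with elements \code{name}, \code{params}
#'   (a \code{\link{model_params}}), \code{X0} (a
#'   \code{\link{swimmer_state}}), \code{horizon}, \code{policy} (a
#'   \code{\link{policy_spec}} or NULL) and \code{problem} (a
#'   \code{\link{optimal_control_problem}} or NULL).
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  bad <- setdiff(names(cfg), ALLOWED_TOP)
  if (length(bad))
    stop("scenario config: unknown field(s) ", paste(bad, collapse = ", "))
  if (is.null(cfg$params)) stop("scenario config: missing 'params' block")
  bad <- setdiff(names(cfg$params), ALLOWED_PAR)
  if (length(bad))
    stop("scenario config: unknown params field(s) ",
         paste(bad, collapse = ", "))
  pr <- cfg$params
  if (is.null(pr$u_max)) stop("scenario config: params.u_max is required")
  if (is.null(pr$v)) pr$v <- 1
  if (is.null(pr$k)) pr$k <- 1
  if (is.null(pr$omega)) stop("scenario config: params.omega is required")
  args <- pr[!vapply(pr, is.null, logical(1))]
  params <- do.call(model_params, args)
  if (is.null(cfg$state0) ||
      !all(c("x", "z", "theta") %in% names(cfg$state0)))
    stop("scenario config: state0 must provide x, z and theta")
  X0 <- swimmer_state(cfg$state0$x, cfg$state0$z, cfg$state0$theta)
  policy <- NULL
  if (!is.null(cfg$policy)) {
    bad <- setdiff(names(cfg$policy), ALLOWED_POL)
    if (length(bad))
      stop("scenario config: unknown policy field(s) ",
           paste(bad, collapse = ", "))
    pl <- cfg$policy
    if (is.null(pl$u_max)) pl$u_max <- params$u_max
    if (identical(pl$kind, "open_loop") && is.null(pl$T_switch))
      pl$T_switch <- switch_time(X0[["z"]], X0[["theta"]], params)
    policy <- policy_spec(kind = pl$kind, u_max = pl$u_max,
                          T_switch = pl$T_switch,
                          phase = if (is.null(pl$phase)) 0 else pl$phase)
  }
  problem <- NULL
  if (!is.null(cfg$problem)) {
    bad <- setdiff(names(cfg$problem), ALLOWED_PRB)
    if (length(bad))
      stop("scenario config: unknown problem field(s) ",
           paste(bad, collapse = ", "))
    pb <- cfg$problem
    problem <- optimal_control_problem(pb$id, X0, params, x1 = pb$x1,
                                       theta1 = pb$theta1, z1 = pb$z1)
  }
  structure(list(name = if (is.null(cfg$name)) basename(path) else cfg$name,
                 params = params, X0 = X0,
                 horizon = cfg$horizon, policy = policy, problem = problem),
            class = "ws_scenario")
}

scenario_to_config <- function(sc) {
  cfg <- list(name = sc$name,
              params = sc$params[c("v", "k", "omega", "u_max", "u_min", "a",
                                   "B2", "include_wall_interaction")],
              state0 = list(x = sc$X0[["x"]], z = sc$X0[["z"]],
                            theta = sc$X0[["theta"]]))
  if (!is.null(sc$horizon)) cfg$horizon <- sc$horizon
  if (!is.null(sc$policy))
    cfg$policy <- sc$policy[!vapply(sc$policy, is.null, logical(1))]
  if (!is.null(sc$problem)) {
    pb <- sc$problem
    cfg$problem <- Filter(Negate(is.null),
                          list(id = pb$problem_id, x1 = pb$x1,
                               theta1 = pb$theta1, z1 = pb$z1))
  }
  if (!is.null(sc$notes)) cfg$notes <- sc$notes
  cfg
}

#' Write a scenario configuration
#'
#' Serialises a scenario (as produced by \code{\link{load_scenario}} or the
#' preset generator) back to YAML; numbers keep full double precision so
#' round trips are lossless.
#'
#' @param scenario a \code{ws_scenario}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  cfg <- scenario_to_config(scenario)
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV holds columns \code{t, x, z, theta, u} at full double precision;
#' a sidecar \code{<path>.json} records the model parameters and the crash
#' flag so a run is reproducible from its outputs.
#'
#' @param traj a \code{ws_trajectory}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  side <- list(params = unclass(attr(traj, "params")),
               crashed = isTRUE(attr(traj, "crashed")),
               crash_time = attr(traj, "crash_time"),
               switch_times = attr(traj, "switch_times"),
               n_samples = nrow(df))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back a trajectory CSV
#'
#' @param path CSV path written by \code{\link{write_trajectory}}.
#' @return A data frame with columns \code{t, x, z, theta, u}.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

fig_preset_list <- function() {
  sc <- list()
  # wall-parallel transport at two characteristic speeds and three wave
  # frequencies; heights back-solved from the characteristic-speed relation
  # at amplitude 5, taking the root beyond the optimal distance 2/k
  for (tag in c(a = 0.62, b = 0.34)) NULL
  specs <- expand.grid(V0 = c(0.62, 0.34), omega = c(4, 8, 12))
  for (i in seq_len(nrow(specs))) {
    V0 <- specs$V0[i]; om <- specs$omega[i]
    z0 <- distance_for_speed(V0, 5, 1, branch = "far")
    nm <- sprintf("fig3%s_w%d", if (V0 == 0.62) "a" else "b", om)
    sc[[nm]] <- structure(list(
      name = nm,
      params = model_params(omega = om, u_max = 5),
      X0 = swimmer_state(0, z0, -pi / 2),
      horizon = NULL, policy = NULL,
      problem = optimal_control_problem(1, swimmer_state(0, z0, -pi / 2),
                                        model_params(omega = om, u_max = 5),
                                        x1 = 2 * pi),
      notes = sprintf("parallel transport preset: |V0| = %g realised at z0 = %.12g with u_max = 5", V0, z0)),
      class = "ws_scenario")
  }
  # reorientation presets at height 2/k
  pairs <- list(a = c(-pi / 4, -3 * pi / 4), b = c(-pi, 0),
                c = c(-pi / 2, pi / 2))
  for (nm in names(pairs)) {
    th <- pairs[[nm]]
    key <- paste0("fig4", nm)
    p <- model_params(omega = 4, u_max = 5)
    X0 <- swimmer_state(0, 2, th[1])
    sc[[key]] <- structure(list(
      name = key, params = p, X0 = X0, horizon = NULL, policy = NULL,
      problem = optimal_control_problem(2, X0, p, theta1 = th[2]),
      notes = "reorientation preset at height 2/k"),
      class = "ws_scenario")
  }
  # policy robustness presets
  mkfig5 <- function(nm, kind, B2, inter) {
    p <- model_params(omega = 4, u_max = 5, B2 = B2,
                      include_wall_interaction = inter)
    X0 <- swimmer_state(0, 3, -pi / 2)
    pol <- if (kind == "open_loop") {
      policy_spec("open_loop", u_max = 5,
                  T_switch = switch_time(3, -pi / 2, p))
    } else policy_spec("feedback", u_max = 5)
    structure(list(name = nm, params = p, X0 = X0, horizon = 5,
                   policy = pol, problem = NULL,
                   notes = "driving-policy preset"),
              class = "ws_scenario")
  }
  sc$fig5a <- mkfig5("fig5a", "open_loop", 0, FALSE)
  sc$fig5b <- mkfig5("fig5b", "feedback", 0, FALSE)
  sc$fig5c <- mkfig5("fig5c", "feedback", -20, TRUE)   # pusher, repelled
  sc$fig5d <- mkfig5("fig5d", "feedback", -100, TRUE)  # strong pusher
  sc$fig5e <- mkfig5("fig5e", "feedback", 20, TRUE)    # puller, attracted
  sc
}

#' Built-in scenario presets
#'
#' Named scenario presets for the parallel-transport study (two
#' characteristic speeds \eqn{|V_0| \in \{0.62, 0.34\}} times wave
#' frequencies \eqn{\omega \in \{4, 8, 12\}}), the three reorientation cases
#' \eqn{(\theta_0, \theta_1) \in \{(-\pi/4, -3\pi/4), (-\pi, 0),
#' (-\pi/2, \pi/2)\}} and the five driving-policy runs from
#' \eqn{(0, 3, -\pi/2)} over \eqn{T = 5} with \eqn{u_{max} = 5}
#' (open loop; feedback; feedback with squirmer-wall interaction for
#' \eqn{B_2 = -20, -100, +20}).
#'
#' @param name preset name, e.g. \code{"fig3a_w4"}, \code{"fig4b"},
#'   \code{"fig5c"}; with \code{name = NULL} the full named list is returned.
#' @return A \code{ws_scenario} or a named list of them.
#' @export
scenario_preset <- function(name = NULL) {
  sc <- fig_preset_list()
  if (is.null(name)) return(sc)
  if (!name %in% names(sc))
    stop("unknown preset '", name, "'; available: ",
         paste(names(sc), collapse = ", "))
  sc[[name]]
}

#' Write all scenario presets as YAML fixtures
#'
#' @param dir output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
make_figure_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sc <- fig_preset_list()
  paths <- character(0)
  for (nm in names(sc)) {
    p <- file.path(dir, paste0(nm, ".yaml"))
    write_scenario(sc[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
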