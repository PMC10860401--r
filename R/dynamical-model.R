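#' Construct a parameterized dynamical model
#'
#' A model couples a transition rule (a vector field for continuous time,
#' a one-step map for discrete time), an observation map, an initial
#' state and optional input signals. Trajectories are produced with
#' [simulateModel()].
#'
#' @param time `"continuous"` or `"discrete"`.
#' @param space A [parameterSpace()].
#' @param x0 Named numeric initial state vector.
#' @param transition For continuous models a function
#'   `function(t, state, theta, input)` returning the state derivative;
#'   for discrete models the next state. `input` is `input_fun(t)` (or
#'   `NULL`).
#' @param observation Function `function(t, state, theta, input)`
#'   returning the named observable vector (constant dimension).
#' @param obs_names Character names of the observable components.
#' @param input_fun Optional function of time returning the input vector
#'   (e.g. daily weather). `NULL` for autonomous models.
#' @param compiled Optional list (`func`, `initfunc`, `dllname`, `parms`)
#'   describing a compiled deSolve right-hand side; `parms(theta)` must
#'   return the numeric parameter vector handed to the solver. Used
#'   automatically by [simulateModel()] for continuous models.
#' @param name Optional model label used in printing and reports.
#'
#' @return An object of class `"dynamicalModel"`.
#' @seealso [epidemicsModel()], [lnasModel()] for ready-made instances.
#' @export
dynamicalModel <- function(time = c("continuous", "discrete"), space, x0,
                           transition, observation, obs_names,
                           input_fun = NULL, compiled = NULL, name = "model") {
  time <- match.arg(time)
  stopifnot(inherits(space, "parameterSpace"), is.function(transition),
            is.function(observation))
  x0 <- as.numeric(x0) |> setNames(names(x0))
  if (is.null(names(x0)) || any(names(x0) == ""))
    names(x0) <- paste0("x", seq_along(x0))
  structure(
    list(time = time, space = space, x0 = x0, transition = transition,
         observation = observation, obs_names = as.character(obs_names),
         input_fun = input_fun, compiled = compiled, name = name),
    class = "dynamicalModel"
  )
}

#' @export
print.dynamicalModel <- function(x, ...) {
  cat(sprintf("<dynamicalModel '%s'> %s time, %d states (%s), %d parameters, observables: %s\n",
              x$name, x$time, length(x$x0), paste(names(x$x0), collapse = ", "),
              length(x$space$names), paste(x$obs_names, collapse = ", ")))
  invisible(x)
}

#' Simulate a model to a trajectory
#'
#' Integrates (continuous time, adaptive explicit Runge-Kutta through
#' deSolve's `ode45` by default) or iterates (discrete time) the model
#' and evaluates the observation map on every grid point. Continuous
#' trajectories are solved directly to the requested grid; there is no
#' interpolation of a coarser solution.
#'
#' @param model A [dynamicalModel()].
#' @param theta Parameter vector (defaults to the space reference). Must
#'   lie inside the domain box.
#' @param times Requested time grid (days), non-empty and strictly
#'   increasing. For discrete models must be consecutive integers
#'   starting at 0.
#' @param rtol,atol Solver tolerances (continuous models only; both must
#'   be positive).
#' @param method deSolve integration method, default `"ode45"`.
#' @param maxsteps Maximum internal solver steps between output times.
#'
#' @return An object of class `"trajectory"`: list with `times`, `states`
#'   (matrix, one row per time), `observables` (matrix, one row per
#'   time). Convert with [as.data.frame()] for CSV export.
#' @examples
#' m <- epidemicsModel()
#' tr <- simulateModel(m, times = seq(0, 12, 2))
#' head(as.data.frame(tr))
#' @export
simulateModel <- function(model, theta = model$space$reference, times,
                          rtol = 1e-8, atol = 1e-10, method = "ode45",
                          maxsteps = 10000) {
  theta <- checkTheta(model$space, theta)
  times <- as.numeric(times)
  if (length(times) == 0 || is.unsorted(times, strictly = TRUE))
    simulationError("times must be non-empty and strictly increasing")
  if (model$time == "discrete") {
    if (!isTRUE(all.equal(times, seq(0, length.out = length(times)))))
      simulationError("discrete models use consecutive integer times from 0")
    states <- matrix(NA_real_, length(times), length(model$x0),
                     dimnames = list(NULL, names(model$x0)))
    x <- model$x0
    states[1L, ] <- x
    for (k in seq_len(length(times) - 1L)) {
      t <- times[k]
      u <- if (!is.null(model$input_fun)) model$input_fun(t) else NULL
      x <- model$transition(t, x, theta, u)
      if (any(!is.finite(x)))
        simulationError(sprintf("non-finite state at time %g", t + 1),
                        time = t + 1)
      states[k + 1L, ] <- x
    }
  } else {
    if (rtol <= 0 || atol <= 0)
      simulationError("solver tolerances must be positive")
    grid <- if (times[1] > 0) c(0, times) else times
    out <- tryCatch(
      suppressWarnings(solveODE(model, theta, grid, rtol, atol, method, maxsteps)),
      error = function(e) simulationError(conditionMessage(e))
    )
    if (nrow(out) < length(grid) || any(!is.finite(out))) {
      bad <- if (nrow(out) > 0) {
        fin <- apply(is.finite(out), 1, all)
        if (all(fin)) grid[nrow(out)] else out[which(!fin)[1], 1]
      } else grid[1]
      simulationError(sprintf("simulation blew up near time %g", bad),
                      time = bad)
    }
    keep <- match(times, grid)
    states <- out[keep, -1, drop = FALSE]
    colnames(states) <- names(model$x0)
  }
  obs <- matrix(NA_real_, length(times), length(model$obs_names),
                dimnames = list(NULL, model$obs_names))
  for (k in seq_along(times)) {
    u <- if (!is.null(model$input_fun)) model$input_fun(times[k]) else NULL
    obs[k, ] <- model$observation(times[k], states[k, ], theta, u)
  }
  structure(list(times = times, states = states, observables = obs,
                 theta = theta, model_name = model$name),
            class = "trajectory")
}

solveODE <- function(model, theta, grid, rtol, atol, method, maxsteps) {
  if (!is.null(model$compiled)) {
    cp <- model$compiled
    deSolve::ode(y = model$x0, times = grid, func = cp$func,
                 parms = cp$parms(theta), dllname = cp$dllname,
                 initfunc = cp$initfunc, method = method,
                 rtol = rtol, atol = atol, maxsteps = maxsteps)
  } else {
    rhs <- function(t, y, parms) {
      u <- if (!is.null(model$input_fun)) model$input_fun(t) else NULL
      list(model$transition(t, y, parms, u))
    }
    deSolve::ode(y = model$x0, times = grid, func = rhs, parms = theta,
                 method = method, rtol = rtol, atol = atol,
                 maxsteps = maxsteps)
  }
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'> %d time points over [%g, %g], states: %s, observables: %s\n",
              x$model_name, length(x$times), min(x$times), max(x$times),
              paste(colnames(x$states), collapse = ", "),
              paste(colnames(x$observables), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  obs <- x$observables
  dup <- colnames(obs) %in% colnames(x$states)
  colnames(obs)[dup] <- paste0("obs_", colnames(obs)[dup])
  data.frame(time = x$times, x$states, obs, check.names = FALSE)
}
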