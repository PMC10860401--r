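#' Noise specifications for observation protocols
#'
#' `noiseAbsolute(sd)` requests additive Gaussian noise with a fixed
#' standard deviation; `noiseRelative(fraction)` requests a standard
#' deviation equal to `fraction` times the time-mean of the component's
#' noise-free values over the protocol times (resolved per trajectory by
#' [resolveNoise()]).
#'
#' @param sd Absolute standard deviation (> 0).
#' @param fraction Fraction of the component's time-mean (> 0).
#' @return A noise-spec list with elements `type` and `value`.
#' @export
noiseAbsolute <- function(sd) {
  stopifnot(is.finite(sd), sd > 0)
  list(type = "absolute", value = sd)
}

#' @rdname noiseAbsolute
#' @export
noiseRelative <- function(fraction) {
  stopifnot(is.finite(fraction), fraction > 0)
  list(type = "relative", value = fraction)
}

#' Define an observation protocol
#'
#' A protocol fixes which observable components are measured, at which
#' times, and with which Gaussian noise. Measurements are always laid
#' out time-major, component-minor: all observed components at t1, then
#' all at t2, and so on. Every index in the package relies on this
#' ordering.
#'
#' @param times Strictly increasing, non-empty observation times (days).
#' @param observed Non-empty character vector of observable component
#'   names.
#' @param noise Either `NULL` (noise-free), a single noise spec applied
#'   to all components, or a named list of specs (one per observed
#'   component). See [noiseAbsolute()] / [noiseRelative()].
#' @return An object of class `"observationProtocol"`.
#' @examples
#' observationProtocol(seq(2, 12, 2), c("I", "N"),
#'                     noise = noiseRelative(0.015))
#' @export
observationProtocol <- function(times, observed, noise = NULL) {
  times <- as.numeric(times)
  if (length(times) == 0 || is.unsorted(times, strictly = TRUE))
    protocolError("observation times must be non-empty and strictly increasing")
  observed <- as.character(observed)
  if (length(observed) == 0) protocolError("observed must be non-empty")
  if (!is.null(noise)) {
    if (!is.null(noise$type)) noise <- setNames(rep(list(noise), length(observed)),
                                                observed)
    if (!all(observed %in% names(noise)))
      protocolError("noise must name every observed component")
    for (k in observed)
      if (!is.finite(noise[[k]]$value) || noise[[k]]$value <= 0)
        protocolError("noise sd values / fractions must be strictly positive")
  }
  structure(list(times = times, observed = observed, noise = noise),
            class = "observationProtocol")
}

#' @export
print.observationProtocol <- function(x, ...) {
  cat(sprintf("<observationProtocol> %d times in [%g, %g], components: %s, noise: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(x$observed, collapse = ", "),
              if (is.null(x$noise)) "none" else
                paste(sprintf("%s=%s(%g)", x$observed,
                              vapply(x$noise[x$observed], `[[`, "", "type"),
                              vapply(x$noise[x$observed], `[[`, 0, "value")),
                      collapse = ", ")))
  invisible(x)
}

## record bookkeeping: component and time of each entry of the flat
## measurement vector, in time-major, component-minor order
protocolRecords <- function(protocol) {
  data.frame(
    component = rep(protocol$observed, times = length(protocol$times)),
    time = rep(protocol$times, each = length(protocol$observed))
  )
}

#' Extract the flat measurement vector of a trajectory
#'
#' Returns the noise-free measurement vector eta(theta): the observed
#' components of the trajectory at the protocol times, flattened
#' time-major, component-minor. Protocol times must lie exactly on the
#' trajectory grid; there is no silent interpolation.
#'
#' @param traj A [simulateModel()] trajectory.
#' @param protocol An [observationProtocol()].
#' @return Named numeric vector of length
#'   `length(times) * length(observed)`.
#' @export
observe <- function(traj, protocol) {
  idx <- match(protocol$times, traj$times)
  if (anyNA(idx))
    protocolError(sprintf("protocol times absent from trajectory grid: %s",
                          paste(protocol$times[is.na(idx)], collapse = ", ")))
  miss <- setdiff(protocol$observed, colnames(traj$observables))
  if (length(miss))
    protocolError(paste("unknown observable component(s):",
                        paste(miss, collapse = ", ")))
  block <- traj$observables[idx, protocol$observed, drop = FALSE]
  rec <- protocolRecords(protocol)
  setNames(as.vector(t(block)), paste0(rec$component, "@", rec$time))
}

#' Resolve the per-record noise standard deviations
#'
#' Absolute specs pass through; relative specs become
#' `fraction * mean(noise-free values over protocol times)` of the
#' component. A relative spec on a component whose time-mean is zero is
#' a degenerate-noise error.
#'
#' @inheritParams observe
#' @return Numeric vector of per-record sds aligned with [observe()].
#' @export
resolveNoise <- function(traj, protocol) {
  if (is.null(protocol$noise))
    protocolError("protocol has no noise specification")
  eta <- observe(traj, protocol)
  rec <- protocolRecords(protocol)
  sds <- numeric(length(eta))
  for (k in protocol$observed) {
    spec <- protocol$noise[[k]]
    rows <- rec$component == k
    if (spec$type == "absolute") {
      sds[rows] <- spec$value
    } else {
      m <- mean(eta[rows])
      if (abs(m) < 1e-12)
        protocolError(sprintf(
          "relative noise on component '%s' with zero time-mean", k))
      sds[rows] <- spec$value * abs(m)
    }
  }
  setNames(sds, names(eta))
}

#' Build a noisy dataset from a measurement vector
#'
#' Adds independent centered Gaussian noise of the given per-record
#' standard deviations to a noise-free measurement vector and packages
#' the result with its bookkeeping (component, time, value, sd) for use
#' in the chi-square objective. With `sd = 0` (noise disabled) the data
#' equal the measurement vector exactly.
#'
#' @param eta Noise-free measurement vector (from [observe()]).
#' @param sds Per-record standard deviations for the chi-square weights;
#'   values of 0 are allowed here only to disable noise.
#' @param protocol The generating [observationProtocol()].
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @param theta Optional generating parameter vector (provenance).
#' @return An object of class `"dataset"`: data frame with columns
#'   `component`, `time`, `value`, `sd`, plus attributes `seed` and
#'   `theta`.
#' @export
makeDataset <- function(eta, sds, protocol, seed = 1, theta = NULL) {
  stopifnot(length(eta) == length(sds))
  rec <- protocolRecords(protocol)
  set.seed(seed)
  values <- as.numeric(eta) + rnorm(length(eta), 0, as.numeric(sds))
  structure(
    data.frame(component = rec$component, time = rec$time,
               value = values, sd = as.numeric(sds)),
    class = c("dataset", "data.frame"), seed = seed, theta = theta
  )
}

#' Simulate a synthetic noisy dataset from a model
#'
#' Convenience wrapper: simulates the model at `theta`, extracts the
#' measurement vector, resolves the protocol's noise specification and
#' draws one noisy dataset.
#'
#' @param model A [dynamicalModel()].
#' @param protocol An [observationProtocol()] with a noise block.
#' @param theta Generating parameters (defaults to the reference).
#' @param seed Integer seed.
#' @param ... Passed to [simulateModel()] (solver options).
#' @return A `"dataset"` (see [makeDataset()]).
#' @examples
#' d <- simulateDataset(epidemicsModel(), epidemicsProtocol(), seed = 1)
#' head(d)
#' @export
simulateDataset <- function(model, protocol, theta = model$space$reference,
                            seed = 1, ...) {
  traj <- simulateModel(model, theta, times = simulationGrid(model, protocol),
                        ...)
  eta <- observe(traj, protocol)
  sds <- resolveNoise(traj, protocol)
  makeDataset(eta, sds, protocol, seed = seed, theta = theta)
}

## time grid on which the model must be simulated to serve a protocol
simulationGrid <- function(model, protocol) {
  if (model$time == "discrete") seq(0, max(protocol$times)) else
    sort(unique(c(0, protocol$times)))
}

#' Read and write datasets as CSV
#'
#' Values and sds are serialized with 17 significant digits so that a
#' write/read round trip is bit-exact.
#'
#' @param dataset A `"dataset"`.
#' @param path File path.
#' @return `readDataset` returns a `"dataset"`; `writeDataset` returns
#'   `path` invisibly.
#' @export
writeDataset <- function(dataset, path) {
  out <- data.frame(component = dataset$component,
                    time = sprintf("%.17g", dataset$time),
                    value = sprintf("%.17g", dataset$value),
                    sd = sprintf("%.17g", dataset$sd))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  raw <- read.csv(path, colClasses = c("character", "character",
                                       "character", "character"))
  structure(
    data.frame(component = raw$component, time = as.numeric(raw$time),
               value = as.numeric(raw$value), sd = as.numeric(raw$sd)),
    class = c("dataset", "data.frame")
  )
}
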