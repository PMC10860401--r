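#' Reference parameters of the plant epidemic model
#'
#' Field-calibrated reference values for the SIR-type stem epidemic:
#' `b` production rate of susceptible stems (day^-1), `kappa` carrying
#' capacity (stems), `lambda0` force of infection (day^-1), `mu` decay
#' rate of the force of infection (day^-1), `d` death rate of infected
#' stems (day^-1).
#'
#' @return Named numeric vector of length 5.
#' @export
epidemicsReference <- function() {
  c(b = 1.177, kappa = 4.876, lambda0 = 0.051, mu = 0.096, d = 0.246)
}

#' Right-hand side of the plant epidemic model
#'
#' Evaluates the vector field of the stem epidemic at one point. The
#' susceptible pool is replenished at rate `b (kappa - N)` with
#' `N = S + I + R`, infection proceeds at the decaying per-susceptible
#' rate `lambda0 exp(-mu t)`, and infected stems die at rate `d`.
#'
#' Two variants are supported. `"as-printed"` uses
#' `dI/dt = lambda0 exp(-mu t) S` (so `I` counts cumulative infections
#' and `d` feeds `R` only). `"removal"` subtracts `d I` from `dI/dt` so
#' that `I` is the standing infected population; under this variant the
#' total `N` obeys `dN/dt = b (kappa - N)` exactly and decouples from
#' the infection parameters. The `"removal"` variant is the package
#' default for the model (see [epidemicsModel()]) because it is the only
#' one under which the documented compensation between `mu` and `d` in
#' the infected dynamics can occur at all.
#'
#' @param t Time (days, >= 0).
#' @param state Numeric vector `(S, I, R)`.
#' @param theta Numeric vector `(b, kappa, lambda0, mu, d)`.
#' @param variant `"as-printed"` or `"removal"`.
#' @return Numeric derivative vector `(dS, dI, dR)`.
#' @examples
#' epidemicsRHS(0, c(0, 0, 0), epidemicsReference())  # (b*kappa, 0, 0)
#' @export
epidemicsRHS <- function(t, state, theta, variant = c("as-printed", "removal")) {
  variant <- match.arg(variant)
  state <- unname(state); theta <- unname(theta)
  N <- state[1] + state[2] + state[3]
  infection <- theta[3] * exp(-theta[4] * t) * state[1]
  dI <- if (variant == "removal") infection - theta[5] * state[2] else infection
  c(theta[1] * (theta[2] - N) - infection, dI, theta[5] * state[2])
}

#' The plant-population epidemic model
#'
#' Builds the continuous-time stem epidemic as a [dynamicalModel()] with
#' observables `I` (infected stems) and `N = S + I + R` (total stems).
#' Parameters and their reference values come from
#' [epidemicsReference()]; all five are positive with domain
#' `(0, Inf)`. The initial state defaults to a bare plot,
#' `(S, I, R) = (0, 0, 0)`: stems are produced by the `b (kappa - N)`
#' term. Integration uses the compiled right-hand side shipped with the
#' package.
#'
#' @param variant Model variant, see [epidemicsRHS()]. Default
#'   `"removal"`.
#' @param x0 Initial state, default `c(S = 0, I = 0, R = 0)`.
#' @param reference Reference parameter vector (defaults to
#'   [epidemicsReference()]).
#' @return A `"dynamicalModel"`.
#' @examples
#' m <- epidemicsModel()
#' tr <- simulateModel(m, times = seq(0, 12, 2))
#' tr$observables
#' @export
epidemicsModel <- function(variant = c("removal", "as-printed"),
                           x0 = c(S = 0, I = 0, R = 0),
                           reference = epidemicsReference()) {
  variant <- match.arg(variant)
  ## parameters are treated as real-valued (profiles and optimizers may
  ## cross zero; a log scale remains available via the positive flags)
  space <- parameterSpace(names(epidemicsReference()), reference,
                          lower = -Inf, upper = Inf, positive = TRUE)
  removal_flag <- as.numeric(variant == "removal")
  dynamicalModel(
    time = "continuous", space = space, x0 = x0,
    transition = function(t, state, theta, input)
      epidemicsRHS(t, state, theta, variant = variant),
    observation = function(t, state, theta, input)
      c(I = unname(state[2]), N = unname(state[1] + state[2] + state[3])),
    obs_names = c("I", "N"),
    compiled = list(func = "epi_derivs", initfunc = "epi_initmod",
                    dllname = "pident",
                    parms = function(theta) c(unname(theta), removal_flag)),
    name = paste0("epidemics-", variant)
  )
}

#' The case-study observation protocol for the epidemic model
#'
#' Infected and total stems observed every other day between day 2 and
#' day 12, each with additive Gaussian noise whose standard deviation is
#' 1.5% of the observable's time-mean.
#'
#' @param noise_fraction Relative noise level (fraction of the
#'   time-mean), default 0.015.
#' @return An [observationProtocol()].
#' @export
epidemicsProtocol <- function(noise_fraction = 0.015) {
  observationProtocol(
    times = seq(2, 12, by = 2), observed = c("I", "N"),
    noise = list(I = noiseRelative(noise_fraction),
                 N = noiseRelative(noise_fraction))
  )
}
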