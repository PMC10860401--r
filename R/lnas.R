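#' Log-normal cumulative distribution parameterized by median and spread
#'
#' The LNAS allocation and senescence kinetics are driven by log-normal
#' CDFs of thermal time specified by a median (degree-days) and a spread
#' parameter. Two readings of the spread are supported: `"sd"` (default)
#' interprets it as the standard deviation of the log-normal variate
#' itself, solved in closed form for the underlying normal sd; `"sdlog"`
#' interprets it directly as the standard deviation of the underlying
#' normal. The `"sd"` reading keeps medians and spreads on comparable
#' degree-day scales (e.g. median 550, spread 950).
#'
#' @param x Evaluation points (thermal time, degree-days). Values
#'   `<= 0` return 0.
#' @param median Median of the log-normal law (> 0).
#' @param spread Spread parameter (> 0), interpreted per `convention`.
#' @param convention `"sd"` or `"sdlog"`.
#' @return CDF values in `[0, 1]`, non-decreasing and continuous in `x`.
#' @examples
#' lognormalCDF(550, 550, 950)  # 0.5 whatever the spread
#' @export
lognormalCDF <- function(x, median, spread, convention = c("sd", "sdlog")) {
  convention <- match.arg(convention)
  if (!is.finite(median) || median <= 0 || !is.finite(spread) || spread <= 0)
    domainError("median and spread must be strictly positive")
  sdlog <- if (convention == "sd") {
    ## variance of LN(meanlog = log(m), sdlog = s) is m^2 v (v - 1),
    ## v = exp(s^2); solve m^2 v (v - 1) = spread^2 for v in closed form
    v <- (1 + sqrt(1 + 4 * (spread / median)^2)) / 2
    sqrt(log(v))
  } else spread
  plnorm(x, meanlog = log(median), sdlog = sdlog)
}

#' LNAS free parameters
#'
#' The eight estimable parameters of the LNAS sugar-beet growth model:
#' radiation-use efficiency `RUE` (g MJ^-1), leaf mass-to-surface
#' conversion `eg` (m^2 g^-1), median/spread of the allocation
#' log-normal `mu_a`, `sigma_a` (degree-days), median/spread of the
#' senescence log-normal `mu_s`, `sigma_s` (degree-days), and the
#' initial and final leaf allocation fractions `gamma0`, `gammaf`
#' (in (0, 1)). Defaults give a realistic sigmoidal yield curve with
#' the synthetic weather of [generateWeather()].
#'
#' @param RUE,eg,mu_a,sigma_a,mu_s,sigma_s,gamma0,gammaf See description.
#' @return Named numeric vector of length 8 in canonical order.
#' @export
lnasParameters <- function(RUE = 3.6, eg = 0.06, mu_a = 550, sigma_a = 950,
                           mu_s = 1700, sigma_s = 400, gamma0 = 0.8,
                           gammaf = 0.15) {
  theta <- c(RUE = RUE, eg = eg, mu_a = mu_a, sigma_a = sigma_a,
             mu_s = mu_s, sigma_s = sigma_s, gamma0 = gamma0, gammaf = gammaf)
  if (any(!is.finite(theta)) || any(theta <= 0))
    domainError("all LNAS parameters must be strictly positive")
  if (gamma0 >= 1 || gammaf >= 1)
    domainError("gamma0 and gammaf must lie in (0, 1)")
  theta
}

#' LNAS fixed constants
#'
#' Constants kept out of the estimation problem: the Beer-Lambert
#' extinction coefficient `kB`, the base temperature `Tb` (deg C) below
#' which no thermal time accumulates, the senescence-onset thermal time
#' `tau_sen` (degree-days), and the initial production `seed_mass`
#' (g m^-2) released at day 0 from seed reserves (the initial leaf and
#' root masses themselves are zero).
#'
#' @param kB,Tb,tau_sen,seed_mass See description.
#' @return Named list.
#' @export
lnasConstants <- function(kB = 0.7, Tb = 0, tau_sen = 500, seed_mass = 0.5) {
  if (!is.finite(kB) || kB <= 0 || seed_mass <= 0)
    domainError("kB and seed_mass must be strictly positive")
  list(kB = kB, Tb = Tb, tau_sen = tau_sen, seed_mass = seed_mass)
}

#' One daily step of the LNAS model
#'
#' Advances the LNAS state (thermal time `tau`, leaf mass `Ql`, root
#' mass `Qr`, cumulative production `cum`) by one day. Green leaf mass
#' is the unsenesced fraction of `Ql`; daily production follows
#' Beer-Lambert interception of the day's radiation, with at most 95%
#' of incident radiation absorbable; the day's production is allocated
#' between leaves and roots by the allocation fraction evaluated at the
#' pre-update thermal time.
#'
#' @param state Named numeric `(tau, Ql, Qr, cum)`.
#' @param theta [lnasParameters()] vector.
#' @param consts [lnasConstants()] list.
#' @param T_t Daily mean temperature (deg C).
#' @param PAR_t Daily photosynthetically active radiation (MJ m^-2).
#' @param bootstrap Extra production added to the day's production
#'   (used by [lnasModel()] to release `seed_mass` at day 0). Default 0.
#' @param convention Spread convention for [lognormalCDF()].
#' @return List with `state` (next state) and `Q` (production of the
#'   day, g m^-2).
#' @export
lnasStep <- function(state, theta, consts, T_t, PAR_t, bootstrap = 0,
                     convention = "sd") {
  tau <- state[["tau"]]; Ql <- state[["Ql"]]; Qr <- state[["Qr"]]
  Gs <- lognormalCDF(tau - consts$tau_sen, theta[["mu_s"]], theta[["sigma_s"]],
                     convention)
  Ga <- lognormalCDF(tau, theta[["mu_a"]], theta[["sigma_a"]], convention)
  Qg <- (1 - Gs) * Ql
  gamma_t <- theta[["gamma0"]] + (theta[["gammaf"]] - theta[["gamma0"]]) * Ga
  Q <- 0.95 * theta[["RUE"]] * PAR_t *
    (1 - exp(-consts$kB * Qg * theta[["eg"]])) + bootstrap
  c(state = list(c(tau = tau + max(0, T_t - consts$Tb),
                   Ql = Ql + gamma_t * Q,
                   Qr = Qr + (1 - gamma_t) * Q,
                   cum = state[["cum"]] + Q)),
    Q = Q)
}

#' The LNAS sugar-beet growth model
#'
#' Builds the discrete-time (daily) LNAS model as a [dynamicalModel()]
#' driven by a weather series of daily temperature and radiation. State:
#' thermal time `tau`, total leaf mass `Ql`, root mass (yield) `Qr` and
#' the cumulative-production bookkeeping `cum` (all masses g m^-2;
#' `Ql + Qr = cum` holds to machine precision). Observables are the
#' green (unsenesced) leaf biomass `Qg` and the yield `Qr`. Day 0
#' releases `seed_mass` as production so growth can start although the
#' initial leaf and root masses are zero.
#'
#' @param parameters Reference parameter vector, see [lnasParameters()].
#' @param constants Fixed constants, see [lnasConstants()].
#' @param weather Data frame with columns `day` (0-based), `T`, `PAR`
#'   covering the simulation horizon, e.g. from [generateWeather()].
#' @param convention Spread convention for [lognormalCDF()].
#' @return A `"dynamicalModel"` (discrete time).
#' @examples
#' w <- generateWeather(151, seed = 1)
#' m <- lnasModel(weather = w)
#' tr <- simulateModel(m, times = 0:150)
#' tail(as.data.frame(tr))
#' @export
lnasModel <- function(parameters = lnasParameters(),
                      constants = lnasConstants(),
                      weather, convention = "sd") {
  stopifnot(all(c("day", "T", "PAR") %in% names(weather)))
  space <- parameterSpace(
    names(parameters), parameters,
    lower = 0,
    upper = ifelse(names(parameters) %in% c("gamma0", "gammaf"), 1, Inf),
    positive = TRUE
  )
  input_fun <- function(t) {
    i <- match(t, weather$day)
    if (is.na(i))
      simulationError(sprintf("weather series does not cover day %g", t))
    c(T = weather$T[i], PAR = weather$PAR[i])
  }
  dynamicalModel(
    time = "discrete", space = space,
    x0 = c(tau = 0, Ql = 0, Qr = 0, cum = 0),
    transition = function(t, state, theta, input) {
      lnasStep(state, theta, constants, input[["T"]], input[["PAR"]],
               bootstrap = if (t == 0) constants$seed_mass else 0,
               convention = convention)$state
    },
    observation = function(t, state, theta, input) {
      Gs <- lognormalCDF(state[["tau"]] - constants$tau_sen, theta[["mu_s"]],
                         theta[["sigma_s"]], convention)
      c(Qg = (1 - Gs) * state[["Ql"]], Qr = state[["Qr"]])
    },
    obs_names = c("Qg", "Qr"),
    input_fun = input_fun, name = "lnas"
  )
}

#' Generate a synthetic daily weather series
#'
#' Seasonal sinusoids with bounded Gaussian perturbations for daily mean
#' temperature (deg C) and photosynthetically active radiation
#' (MJ m^-2, clamped at 0). Day 0 corresponds to a spring sowing; the
#' sinusoid peaks near mid-summer. Reproducible given `seed`.
#'
#' @param n_days Number of days (day indices `0:(n_days-1)`).
#' @param seed Integer RNG seed.
#' @param profile Named list overriding any of `t_mean`, `t_amp`,
#'   `t_sd`, `p_mean`, `p_amp`, `p_sd`, `peak_day` (day of the seasonal
#'   maximum relative to sowing).
#' @return Data frame with columns `day`, `T`, `PAR`.
#' @examples
#' w <- generateWeather(10, seed = 7)
#' stopifnot(all(w$PAR >= 0))
#' @export
generateWeather <- function(n_days, seed = 1, profile = list()) {
  stopifnot(n_days >= 1)
  p <- modifyList(list(t_mean = 16, t_amp = 6, t_sd = 2,
                       p_mean = 7, p_amp = 3.5, p_sd = 1.5,
                       peak_day = 80), profile)
  day <- seq_len(n_days) - 1
  season <- sin(2 * pi * (day - p$peak_day) / 365 + pi / 2)
  set.seed(seed)
  Temp <- p$t_mean + p$t_amp * season + rnorm(n_days, 0, p$t_sd)
  PAR <- pmax(0, p$p_mean + p$p_amp * season + rnorm(n_days, 0, p$p_sd))
  data.frame(day = day, T = Temp, PAR = PAR)
}

#' The case-study observation protocol for LNAS
#'
#' Green leaf biomass and yield observed daily between day 25 and day
#' 150, with additive Gaussian noise of absolute standard deviation 0.1
#' g m^-2 by default (a relative mode is available through
#' [noiseRelative()]).
#'
#' @param times Observation days, default `25:150`.
#' @param sd Absolute noise standard deviation, default 0.1.
#' @return An [observationProtocol()].
#' @export
lnasProtocol <- function(times = 25:150, sd = 0.1) {
  observationProtocol(times = times, observed = c("Qg", "Qr"),
                      noise = list(Qg = noiseAbsolute(sd),
                                   Qr = noiseAbsolute(sd)))
}
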