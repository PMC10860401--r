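#' Profile-likelihood risk index
#'
#' The risk index of parameter i is `r_i = 1 / sup { alpha in (0, 1) :
#' the PLCI at level alpha has finite length }`. A risk index close to 1
#' means the parameter stays practically identifiable at almost every
#' confidence level; a large index means even modest confidence levels
#' already produce an unbounded interval; an empty finite set (a
#' parameter with no influence on the observables) gives an infinite risk with
#' the unidentifiable flag set.
#'
#' Because PLCIs are nested in alpha, finiteness is monotone and the
#' supremum is found by bisection on alpha with tolerance `alpha_tol`.
#' Each finiteness probe reuses one profile curve marched over the whole
#' search box (never stopping at the first threshold crossing, so
#' disconnected below-threshold regions are handled): a level is finite
#' exactly when, on both sides, the profile tail at the box edge stays
#' above `chi2_min + qchisq(alpha, 1)` (a tail still rising at the edge
#' supports every level).
#'
#' @param objective A [chi2Objective()].
#' @param parameter Parameter name or index.
#' @param alpha_tol Bisection tolerance on alpha (default 0.005).
#' @param profile Optional precomputed full-box [profileLikelihood()]
#'   curve.
#' @param plateau_tol Tail-slope plateau tolerance, see [plci()].
#' @param ... Passed to [profileLikelihood()] when `profile` is missing.
#' @return Object of class `"riskResult"`: list with `sup_alpha`,
#'   `risk` (`= 1/sup_alpha` exactly), `unidentifiable`, `side_caps`,
#'   `box_radius`, `alpha_tol`, `parameter`, `name`, `profile`.
#' @examples
#' \donttest{
#' m <- epidemicsModel()
#' d <- simulateDataset(m, epidemicsProtocol(), seed = 1)
#' obj <- chi2Objective(m, epidemicsProtocol(), d)
#' riskIndex(obj, "kappa")
#' }
#' @export
riskIndex <- function(objective, parameter, alpha_tol = 0.005,
                      profile = NULL, plateau_tol = 1e-3, ...) {
  stopifnot(alpha_tol > 0, alpha_tol < 0.5)
  if (is.null(profile))
    profile <- profileLikelihood(objective, parameter, ...)
  caps <- sideCaps(profile, plateau_tol = plateau_tol)
  cap <- min(caps$lower, caps$upper)
  finiteAt <- function(alpha) qchisq(alpha, df = 1) <= cap
  if (!finiteAt(alpha_tol)) {
    return(structure(
      list(parameter = profile$parameter, name = profile$name,
           sup_alpha = 0, risk = Inf, unidentifiable = TRUE,
           side_caps = caps, box_radius = profile$box_radius,
           alpha_tol = alpha_tol, profile = profile),
      class = "riskResult"))
  }
  lo <- alpha_tol; hi <- 1
  while (hi - lo > alpha_tol) {
    mid <- (lo + hi) / 2
    if (finiteAt(mid)) lo <- mid else hi <- mid
  }
  structure(
    list(parameter = profile$parameter, name = profile$name,
         sup_alpha = lo, risk = 1 / lo, unidentifiable = FALSE,
         side_caps = caps, box_radius = profile$box_radius,
         alpha_tol = alpha_tol, profile = profile),
    class = "riskResult"
  )
}

#' @export
print.riskResult <- function(x, ...) {
  if (x$unidentifiable)
    cat(sprintf("Risk index of '%s': Inf (practically unidentifiable at every probed level)\n",
                x$name))
  else
    cat(sprintf("Risk index of '%s': %.3f (sup alpha = %.4f, bisection tol %g)\n",
                x$name, x$risk, x$sup_alpha, x$alpha_tol))
  invisible(x)
}

#' Risk indices and intervals for several parameters
#'
#' Convenience wrapper running [riskIndex()] (and a PLCI at a requested
#' level where it is finite) for a set of parameters, sharing the global
#' fit.
#'
#' @param objective A [chi2Objective()].
#' @param parameters Names or indices (default: all).
#' @param alpha Level at which to also report a PLCI.
#' @param ... Passed to [riskIndex()] / [profileLikelihood()].
#' @return Data frame with one row per parameter: `parameter`,
#'   `estimate`, `lower`, `upper`, `finite_lower`, `finite_upper`,
#'   `sup_alpha`, `risk`.
#' @export
riskTable <- function(objective, parameters = NULL, alpha = 0.95, ...) {
  nms <- objective$model$space$names
  if (is.null(parameters)) parameters <- nms
  fit <- fitModel(objective)
  rows <- lapply(parameters, function(pn) {
    prof <- profileLikelihood(objective, pn, fit = fit, ...)
    rk <- riskIndex(objective, pn, profile = prof)
    ci <- plci(objective, pn, alpha = min(alpha, max(rk$sup_alpha, 0.01)),
               profile = prof)
    data.frame(parameter = rk$name, estimate = unname(fit$par[rk$parameter]),
               lower = ci$lower, upper = ci$upper,
               finite_lower = ci$finite[["lower"]],
               finite_upper = ci$finite[["upper"]],
               sup_alpha = rk$sup_alpha, risk = rk$risk)
  })
  do.call(rbind, rows)
}
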