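#' Profile likelihood of one parameter
#'
#' For each grid value of the profiled parameter, the chi-square
#' objective is minimized over all other (nuisance) parameters,
#' warm-starting each point from its neighbour's argmin and marching
#' outward from the global fit in both directions. The grid is
#' geometric: steps grow by `grow` away from the fit so that the whole
#' search box is covered in a few dozen points; the profile is later
#' refined by bracketed root finding wherever a threshold crossing is
#' needed, so the march only has to shape the curve. A monotone
#' re-minimization guard re-runs any point from the fit's nuisance
#' values when its profiled value jumps above its neighbour's by more
#' than `jump_tol`, and keeps the better of the two runs.
#'
#' The march always covers the whole box rather than stopping at the
#' first threshold crossing, so that disconnected below-threshold
#' regions (bimodal profiles) are seen by the risk index.
#'
#' @param objective A [chi2Objective()].
#' @param parameter Parameter name or index to profile.
#' @param fit Optional result of [fitModel()] (computed if missing).
#' @param box_radius Half-width of the search box on the working scale;
#'   default `1000 * max(|psi_hat_i|, 1)`.
#' @param step0 Initial step on the working scale; default
#'   `0.02 * max(|psi_hat_i|, 1)`.
#' @param grow Geometric growth factor of the marching step (> 1).
#' @param max_points Cap on grid points per side.
#' @param nuisance_control `optim` control for the nuisance
#'   minimizations (`maxit`, `reltol`).
#' @param jump_tol Chi-square jump above the neighbouring point that
#'   triggers the re-minimization guard.
#' @param fit_control Control passed to [fitModel()] when `fit` is
#'   missing.
#' @return Object of class `"profileCurve"`: list with `psi` (sorted
#'   working-scale grid), `theta` (natural scale), `chi2PL`,
#'   `nuisance` (working-scale argmins, one row per grid point),
#'   `chi2min`, `fit`, `parameter`, `name`, `box_radius`.
#' @seealso [plci()], [riskIndex()]
#' @export
profileLikelihood <- function(objective, parameter, fit = NULL,
                              box_radius = NULL, step0 = NULL, grow = 1.7,
                              max_points = 200,
                              nuisance_control = list(maxit = 600, reltol = 1e-9),
                              jump_tol = 10, fit_control = list()) {
  i <- resolveParameter(objective, parameter)
  if (is.null(fit)) fit <- fitModel(objective, control = fit_control)
  fn <- workingChi2(objective)
  psi_hat <- fit$working
  p <- length(psi_hat)
  center <- psi_hat[i]
  if (is.null(box_radius)) box_radius <- 1000 * max(abs(center), 1)
  if (is.null(step0)) step0 <- 0.02 * max(abs(center), 1)
  deltas <- step0 * cumprod(rep(grow, max_points)) / grow
  deltas <- deltas[deltas <= box_radius]
  if (length(deltas) == 0 || max(deltas) < box_radius)
    deltas <- c(deltas, box_radius)

  profilePoint <- function(value, start_nuis) {
    if (p == 1L) {
      psi <- psi_hat; psi[i] <- value
      return(list(value = fn(psi), nuis = numeric(0), conv = TRUE))
    }
    obj_nuis <- function(nu) {
      psi <- psi_hat; psi[i] <- value; psi[-i] <- nu
      fn(psi)
    }
    o <- nmOptim(start_nuis, obj_nuis, control = nuisance_control)
    list(value = o$value, nuis = o$par, conv = o$convergence == 0)
  }

  marchSide <- function(sign) {
    vals <- numeric(0); nuis <- list(); conv <- logical(0)
    start <- if (p > 1L) psi_hat[-i] else numeric(0)
    prev_val <- fit$value
    for (d in deltas) {
      pt <- profilePoint(center + sign * d, start)
      if (pt$value > prev_val + jump_tol) {
        retry <- profilePoint(center + sign * d,
                              if (p > 1L) psi_hat[-i] else numeric(0))
        if (retry$value < pt$value) pt <- retry
      }
      vals <- c(vals, pt$value); nuis <- c(nuis, list(pt$nuis))
      conv <- c(conv, pt$conv)
      start <- if (p > 1L) pt$nuis else numeric(0)
      prev_val <- pt$value
    }
    list(psi = center + sign * deltas, vals = vals, nuis = nuis, conv = conv)
  }

  left <- marchSide(-1); right <- marchSide(+1)
  psi_grid <- c(rev(left$psi), center, right$psi)
  chi2PL <- c(rev(left$vals), fit$value, right$vals)
  conv <- c(rev(left$conv), fit$converged, right$conv)
  nuis <- c(rev(left$nuis),
            list(if (p > 1L) psi_hat[-i] else numeric(0)), right$nuis)
  ## re-polish non-converged points in the threshold-relevant band
  ## (excess < 50 covers every usable confidence level), then apply the
  ## profile-quality criterion to that band only: far tails sit on the
  ## failure-penalty plateau where convergence is meaningless
  chi2ref <- min(fit$value, min(chi2PL))
  relevant <- chi2PL < chi2ref + 50
  for (k in which(relevant & !conv)) {
    if (p == 1L) next
    redo <- nmOptim(nuis[[k]], function(nu) {
      psi <- psi_hat; psi[i] <- psi_grid[k]; psi[-i] <- nu
      fn(psi)
    }, control = modifyList(nuisance_control,
                            list(maxit = 2 * (nuisance_control$maxit %||% 800))))
    if (redo$value <= chi2PL[k]) {
      chi2PL[k] <- redo$value; nuis[[k]] <- redo$par
    }
    conv[k] <- redo$convergence == 0
  }
  if (mean(!conv[relevant]) > 0.2)
    stop_pident("pident_profile_error", sprintf(
      "profile of '%s': %d%% of threshold-relevant grid points did not converge",
      objective$model$space$names[i], round(100 * mean(!conv[relevant]))))
  theta_grid <- vapply(psi_grid, function(v) {
    psi <- psi_hat; psi[i] <- v
    objective$transform$from(psi)[i]
  }, numeric(1))
  structure(
    list(parameter = i, name = objective$model$space$names[i],
         psi = psi_grid, theta = theta_grid, chi2PL = chi2PL,
         converged = conv, nuisance = nuis, center = center,
         chi2min = min(fit$value, min(chi2PL)), fit = fit,
         box_radius = box_radius, objective = objective,
         nuisance_control = nuisance_control),
    class = "profileCurve"
  )
}

resolveParameter <- function(objective, parameter) {
  nms <- objective$model$space$names
  if (is.character(parameter)) {
    i <- match(parameter, nms)
    if (is.na(i)) domainError(paste("unknown parameter:", parameter))
    i
  } else as.integer(parameter)
}

#' @export
print.profileCurve <- function(x, ...) {
  cat(sprintf("<profileCurve '%s'> %d points, theta in [%g, %g], chi2 min %g\n",
              x$name, length(x$psi), min(x$theta), max(x$theta), x$chi2min))
  invisible(x)
}

#' @export
as.data.frame.profileCurve <- function(x, ...) {
  data.frame(theta = x$theta, psi = x$psi, chi2PL = x$chi2PL,
             converged = x$converged)
}

## profiled chi2 at an arbitrary working-scale value, warm-started from
## the stored argmin of the nearest grid point
profileValueFun <- function(curve) {
  obj <- curve$objective
  fn <- workingChi2(obj)
  i <- curve$parameter
  psi_hat <- curve$fit$working
  p <- length(psi_hat)
  function(value) {
    if (p == 1L) {
      psi <- psi_hat; psi[i] <- value
      return(fn(psi))
    }
    k <- which.min(abs(curve$psi - value))
    start <- curve$nuisance[[k]]
    o <- nmOptim(start, function(nu) {
      psi <- psi_hat; psi[i] <- value; psi[-i] <- nu
      fn(psi)
    }, control = curve$nuisance_control)
    o$value
  }
}

## per-side tail analysis of a profile curve:
##   cap = the largest threshold excess for which the side still yields a
##   bounded below-threshold region. Inf when the profile is still rising
##   at the box edge; the tail-window maximum when it has plateaued.
sideCaps <- function(curve, plateau_tol = 1e-3, window = 5) {
  excess <- curve$chi2PL - curve$chi2min
  capFor <- function(idx_ordered) {
    if (length(idx_ordered) == 0) return(0)
    tail_idx <- idx_ordered[seq(max(1, length(idx_ordered) - window + 1),
                                length(idx_ordered))]
    if (length(tail_idx) < 2) return(excess[tail_idx[1]])
    slope <- abs(diff(range(excess[tail_idx]))) /
      abs(diff(range(curve$psi[tail_idx])))
    if (slope < plateau_tol) max(excess[tail_idx]) else Inf
  }
  center_k <- which.min(abs(curve$psi - curve$center))
  list(lower = capFor(rev(seq_len(center_k - 1))),
       upper = capFor(seq(center_k + 1, length.out = length(curve$psi) - center_k)))
}

#' Profile-likelihood confidence interval
#'
#' The PLCI of parameter i at level alpha is bounded by the nearest
#' crossings, on each side of the fit, of the profiled chi-square with
#' `chi2_min + qchisq(alpha, 1)`. Crossings are bracketed on the
#' profile grid and refined by root finding on the continuous profiled
#' objective. A side is flagged infinite when the march reached the
#' search-box edge with the profile still below the threshold and the
#' tail slope below the plateau tolerance (practical nonidentifiability
#' at that level). Endpoints are reported on the natural scale.
#'
#' @param objective A [chi2Objective()].
#' @param parameter Parameter name or index.
#' @param alpha Confidence level in (0, 1).
#' @param profile Optional precomputed [profileLikelihood()] curve
#'   (computed if missing); pass it when requesting several levels.
#' @param plateau_tol Tail-slope threshold (chi-square units per unit of
#'   the working scale) below which a below-threshold tail is declared a
#'   plateau.
#' @param ... Passed to [profileLikelihood()] when `profile` is missing.
#' @return Object of class `"confidenceInterval"`: list with `lower`,
#'   `upper` (natural scale; `-Inf`/`Inf` for infinite sides), `finite`
#'   (logical pair), `alpha`, `delta`, `parameter`, `name`.
#' @export
plci <- function(objective, parameter, alpha = 0.95, profile = NULL,
                 plateau_tol = 1e-3, ...) {
  if (alpha <= 0 || alpha >= 1) domainError("alpha must lie in (0, 1)")
  if (is.null(profile))
    profile <- profileLikelihood(objective, parameter, ...)
  i <- profile$parameter
  target <- profile$chi2min + qchisq(alpha, df = 1)
  pfun <- profileValueFun(profile)
  caps <- sideCaps(profile, plateau_tol = plateau_tol)
  center_k <- which.min(abs(profile$psi - profile$center))

  solveSide <- function(idx_ordered, cap) {
    ## idx_ordered walks outward from the fit
    prev_psi <- profile$center
    prev_val <- profile$chi2min
    for (k in idx_ordered) {
      if (profile$chi2PL[k] >= target) {
        bracket <- sort(c(prev_psi, profile$psi[k]))
        root <- uniroot(function(v) pfun(v) - target,
                        lower = bracket[1], upper = bracket[2],
                        tol = 1e-7 * max(1, abs(profile$psi[k])))$root
        return(list(psi = root, finite = TRUE))
      }
      prev_psi <- profile$psi[k]; prev_val <- profile$chi2PL[k]
    }
    if (is.finite(cap) && cap < qchisq(alpha, 1))
      list(psi = NA_real_, finite = FALSE)
    else
      list(psi = NA_real_, finite = NA)  # edge reached while still rising
  }

  lo <- solveSide(rev(seq_len(center_k - 1)), caps$lower)
  hi <- solveSide(seq(center_k + 1, length.out = length(profile$psi) - center_k),
                  caps$upper)
  back <- function(v) {
    if (is.na(v)) return(v)
    psi <- profile$fit$working; psi[i] <- v
    objective$transform$from(psi)[i]
  }
  structure(
    list(parameter = i, name = profile$name, alpha = alpha,
         delta = qchisq(alpha, 1),
         lower = if (isTRUE(lo$finite)) back(lo$psi) else -Inf,
         upper = if (isTRUE(hi$finite)) back(hi$psi) else Inf,
         finite = c(lower = isTRUE(lo$finite), upper = isTRUE(hi$finite)),
         estimate = profile$fit$par[i], profile = profile),
    class = "confidenceInterval"
  )
}

#' @export
print.confidenceInterval <- function(x, ...) {
  cat(sprintf("PLCI of '%s' at alpha = %g: [%g, %g]%s\n", x$name, x$alpha,
              x$lower, x$upper,
              if (!all(x$finite)) "  (infinite side: practically nonidentifiable at this level)"
              else ""))
  invisible(x)
}
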