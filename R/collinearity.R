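#' Scaled sensitivity matrix of a model under a protocol
#'
#' Computes `S[i, j] = (dtheta_j / SC_i) * d eta_i / d theta_j` at the
#' reference point by central finite differences of the noise-free
#' measurement vector. Rows are scaled by observable normalization
#' constants `SC_i`, columns by the per-parameter uncertainty ranges
#' `dtheta_j`. Because the collinearity index renormalizes columns to
#' unit length, it is invariant to any positive rescaling of `dtheta`;
#' the scaling is kept for reporting `S` itself.
#'
#' Row scalings on offer: `"component"` (default) divides each record by
#' the time-mean of its component's noise-free values; `"global"` uses a
#' single constant, the mean of all noise-free values (the convention
#' under which the epidemic case study's published index table is
#' recovered); `"none"` applies no row scaling. A custom positive vector
#' can be passed through `sc`. A component time-mean below 1e-12 in
#' magnitude falls back to 1 with a warning.
#'
#' Solver tolerances are tightened well below the finite-difference
#' truncation error so that integration noise does not contaminate the
#' derivative estimates.
#'
#' @param model A [dynamicalModel()].
#' @param protocol An [observationProtocol()].
#' @param theta Evaluation point, default the reference; must lie
#'   strictly inside the domain box.
#' @param dtheta Per-parameter uncertainty ranges (> 0). Default
#'   `pmax(abs(theta), 1e-8)`, i.e. 100% relative uncertainty.
#' @param rel_step Relative central-difference step; the absolute step
#'   for parameter j is `rel_step * max(|theta_j|, 1)`.
#' @param scaling `"component"`, `"global"` or `"none"`.
#' @param sc Optional explicit vector of per-record normalization
#'   constants (overrides `scaling`).
#' @param rtol,atol Solver tolerances used for the sensitivity runs.
#' @return Object of class `"sensitivityMatrix"`: list with `entries`
#'   (records x parameters), `dtheta`, `SC`, `theta`, `records`
#'   (component/time bookkeeping) and `fd` (scheme metadata).
#' @examples
#' S <- sensitivityMatrix(epidemicsModel(), epidemicsProtocol())
#' round(S$entries[1:3, ], 3)
#' @export
sensitivityMatrix <- function(model, protocol, theta = model$space$reference,
                              dtheta = NULL, rel_step = 1e-4,
                              scaling = c("component", "global", "none"),
                              sc = NULL, rtol = 1e-10, atol = 1e-12) {
  scaling <- match.arg(scaling)
  theta <- checkTheta(model$space, theta)
  p <- length(theta)
  if (is.null(dtheta)) dtheta <- pmax(abs(theta), 1e-8)
  dtheta <- rep_len(as.numeric(dtheta), p)
  if (any(dtheta <= 0)) domainError("dtheta must be positive componentwise")
  grid <- simulationGrid(model, protocol)
  solverArgs <- if (model$time == "continuous")
    list(rtol = rtol, atol = atol) else list()
  etaAt <- function(th, who) {
    tryCatch(
      observe(do.call(simulateModel, c(list(model, th, times = grid),
                                       solverArgs)), protocol),
      pident_simulation_error = function(e) simulationError(
        sprintf("simulation failed while perturbing parameter '%s': %s",
                who, conditionMessage(e)), parameter = who)
    )
  }
  eta0 <- etaAt(theta, "(reference)")
  n <- length(eta0)
  J <- matrix(NA_real_, n, p, dimnames = list(names(eta0), names(theta)))
  steps <- numeric(p)
  for (j in seq_len(p)) {
    h <- rel_step * max(abs(theta[j]), 1)
    steps[j] <- h
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (etaAt(up, names(theta)[j]) - etaAt(dn, names(theta)[j])) / (2 * h)
  }
  rec <- protocolRecords(protocol)
  if (is.null(sc)) {
    sc <- switch(scaling,
      component = {
        m <- tapply(eta0, rec$component, mean)
        out <- abs(as.numeric(m[rec$component]))
        if (any(out < 1e-12)) {
          warning("component time-mean below 1e-12; SC set to 1 for those records")
          out[out < 1e-12] <- 1
        }
        out
      },
      global = rep(abs(mean(eta0)), n),
      none = rep(1, n))
  } else {
    sc <- rep_len(as.numeric(sc), n)
    if (any(sc <= 0)) domainError("sc must be positive")
  }
  entries <- sweep(J / sc, 2, dtheta, "*")
  if (any(!is.finite(entries)))
    simulationError("non-finite sensitivity entries")
  structure(
    list(entries = entries, dtheta = setNames(dtheta, names(theta)),
         SC = sc, theta = theta, records = rec,
         fd = list(scheme = "central", rel_step = rel_step, steps = steps,
                   scaling = scaling)),
    class = "sensitivityMatrix"
  )
}

#' @export
print.sensitivityMatrix <- function(x, ...) {
  cat(sprintf("<sensitivityMatrix> %d records x %d parameters (central FD, rel_step %g, scaling '%s')\n",
              nrow(x$entries), ncol(x$entries), x$fd$rel_step, x$fd$scaling))
  invisible(x)
}

## smallest eigenvalue of the unit-normalized Gram matrix of S[, K];
## gamma = 1/sqrt(lambda_min), with Inf below the numeric floor
gammaOf <- function(entries, K, floor_frac = 1e-12) {
  M <- entries[, K, drop = FALSE]
  norms <- sqrt(colSums(M^2))
  if (any(norms == 0)) return(Inf)
  M <- sweep(M, 2, norms, "/")
  G <- crossprod(M)
  lam <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  ## Gram trace equals |K| after normalization; floor relative to it
  if (lam <= floor_frac * sum(diag(G))) return(Inf)
  1 / sqrt(lam)
}

#' Collinearity index of a parameter subset
#'
#' The collinearity index `gamma_K` of subset K is
#' `1 / sqrt(lambda_min)` where `lambda_min` is the smallest eigenvalue
#' of the Gram matrix of the unit-normalized columns of the scaled
#' sensitivity matrix restricted to K. It is always `>= 1`; a zero
#' column, or a `lambda_min` at or below the numeric floor (1e-12 of the
#' Gram trace), yields `Inf` by convention. Singleton subsets of a
#' nonzero column give exactly 1.
#'
#' @param S A [sensitivityMatrix()] (or a plain numeric matrix).
#' @param subset Parameter names or column indices (non-empty).
#' @return `gamma_K` in `[1, Inf]`.
#' @examples
#' S <- sensitivityMatrix(epidemicsModel(), epidemicsProtocol())
#' collinearityIndex(S, c("mu", "d"))
#' @export
collinearityIndex <- function(S, subset) {
  entries <- if (inherits(S, "sensitivityMatrix")) S$entries else as.matrix(S)
  if (length(subset) == 0) domainError("subset must be non-empty")
  if (is.character(subset)) {
    idx <- match(subset, colnames(entries))
    if (anyNA(idx))
      domainError(paste("unknown parameter(s):",
                        paste(subset[is.na(idx)], collapse = ", ")))
    subset <- idx
  }
  gammaOf(entries, subset)
}

#' Collinearity indices of all parameter subsets in a size range
#'
#' Enumerates every subset with `min_size <= |K| <= max_size` and
#' reports `gamma_K` with its compensation-percentage interpretation,
#' sorted by decreasing index. Subset inclusion can only increase the
#' index (eigenvalue interlacing), so the table's head shows the worst
#' compensation structures.
#'
#' @inheritParams collinearityIndex
#' @param min_size,max_size Subset size range (default pairs up to all
#'   parameters).
#' @param cap Refuse enumerations with more subsets than this (default
#'   `2^16`).
#' @return A data frame (class `"collinearitySet"`) with columns
#'   `subset`, `size`, `gamma`, `compensation`.
#' @examples
#' S <- sensitivityMatrix(epidemicsModel(), epidemicsProtocol())
#' head(subsetCollinearity(S, 2, 2))  # all pairs
#' @export
subsetCollinearity <- function(S, min_size = 2,
                               max_size = NULL, cap = 2^16) {
  entries <- if (inherits(S, "sensitivityMatrix")) S$entries else as.matrix(S)
  p <- ncol(entries)
  if (is.null(max_size)) max_size <- p
  stopifnot(min_size >= 1, max_size <= p, min_size <= max_size)
  sizes <- min_size:max_size
  count <- sum(choose(p, sizes))
  if (count > cap)
    stop_pident("pident_cap_error", sprintf(
      "enumeration of %d subsets exceeds the cap (%d); raise 'cap' to proceed",
      count, cap))
  subs <- unlist(lapply(sizes, function(k) combn(p, k, simplify = FALSE)),
                 recursive = FALSE)
  gam <- vapply(subs, function(K) gammaOf(entries, K), numeric(1))
  nm <- colnames(entries) %||% paste0("p", seq_len(p))
  out <- data.frame(
    subset = vapply(subs, function(K) paste(nm[K], collapse = "+"), ""),
    size = lengths(subs), gamma = gam,
    compensation = compensationPercent(gam)
  )
  out <- out[order(-out$gamma), ]
  rownames(out) <- NULL
  class(out) <- c("collinearitySet", "data.frame")
  out
}

#' Compensation percentage of a collinearity index
#'
#' A change in the output caused by shifting one parameter of the subset
#' can be compensated up to `(1 - 1/gamma) * 100` percent by shifting
#' the others; an index of 15 therefore means 93% compensation, and an
#' infinite index 100%.
#'
#' @param gamma Collinearity index value(s), each `>= 1` (Inf allowed).
#' @return Percentages in `[0, 100]`.
#' @examples
#' round(compensationPercent(15))  # 93
#' @export
compensationPercent <- function(gamma) {
  if (any(is.na(gamma)) || any(gamma < 1))
    domainError("collinearity indices must be >= 1")
  ifelse(is.infinite(gamma), 100, (1 - 1 / gamma) * 100)
}

#' Prior-averaged (mean) collinearity indices
#'
#' Local collinearity indices depend strongly on the evaluation point.
#' When no trustworthy reference is available, indices can be averaged
#' over a prior on the parameters: draws are taken from `prior`, the
#' index of each requested subset is computed at each draw, and the
#' per-subset sample mean is reported with its Monte-Carlo standard
#' error. Draws at which the simulation fails or the index is infinite
#' are counted separately and excluded from the mean.
#'
#' @param model,protocol As in [sensitivityMatrix()].
#' @param subsets List of parameter subsets (names or indices); default
#'   all pairs.
#' @param n_samples Number of prior draws.
#' @param seed Integer seed.
#' @param prior Function `function(n)` returning an `n x p` matrix of
#'   draws. Default: componentwise log-normal centered at the reference
#'   with standard deviation `prior_log_sd` on the log scale.
#' @param prior_log_sd Log-scale sd of the default prior (0 gives the
#'   degenerate prior: every draw equals the reference).
#' @param ... Passed to [sensitivityMatrix()].
#' @return Data frame with columns `subset`, `mean_gamma`, `mc_se`,
#'   `n_valid`, `n_infinite`, `n_failed`.
#' @export
meanCollinearity <- function(model, protocol, subsets = NULL,
                             n_samples = 100, seed = 1, prior = NULL,
                             prior_log_sd = 1, ...) {
  stopifnot(n_samples >= 1)
  theta0 <- model$space$reference
  p <- length(theta0)
  if (is.null(prior))
    prior <- function(n) {
      z <- matrix(rnorm(n * p, 0, prior_log_sd), n, p)
      sweep(exp(z), 2, theta0, "*")
    }
  if (is.null(subsets))
    subsets <- combn(p, 2, simplify = FALSE)
  set.seed(seed)
  draws <- prior(n_samples)
  vals <- matrix(NA_real_, n_samples, length(subsets))
  failed <- logical(n_samples)
  for (s in seq_len(n_samples)) {
    S <- tryCatch(
      sensitivityMatrix(model, protocol, theta = draws[s, ], ...),
      pident_error = function(e) NULL)
    if (is.null(S)) { failed[s] <- TRUE; next }
    vals[s, ] <- vapply(subsets, function(K) collinearityIndex(S, K),
                        numeric(1))
  }
  nm <- vapply(subsets, function(K)
    paste(if (is.character(K)) K else model$space$names[K], collapse = "+"), "")
  finite_mean <- function(v) {
    ok <- is.finite(v)
    c(mean = if (any(ok)) mean(v[ok]) else NA_real_,
      se = if (sum(ok) > 1) sd(v[ok]) / sqrt(sum(ok)) else NA_real_,
      n = sum(ok), inf = sum(is.infinite(v), na.rm = TRUE))
  }
  stats <- t(apply(vals, 2, finite_mean))
  data.frame(subset = nm, mean_gamma = stats[, "mean"], mc_se = stats[, "se"],
             n_valid = as.integer(stats[, "n"]),
             n_infinite = as.integer(stats[, "inf"]),
             n_failed = sum(failed))
}
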