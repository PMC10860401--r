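#' Define a parameter space
#'
#' A parameter space couples the parameter names with a reference vector
#' (the point around which local identifiability diagnostics are taken),
#' box domains, and per-parameter flags marking which components are
#' strictly positive and therefore eligible for a log reparameterization.
#'
#' @param names Character vector of unique parameter identifiers.
#' @param reference Numeric reference vector, same length as `names`.
#'   Must lie strictly inside the domain box.
#' @param lower,upper Numeric vectors (recycled if length 1) giving the
#'   open domain box; `-Inf`/`Inf` allowed.
#' @param positive Logical vector (recycled if length 1): is the
#'   parameter constrained positive (log-transformable)? Defaults to
#'   `reference > 0 & lower >= 0`.
#'
#' @return An object of class `"parameterSpace"`: a list with elements
#'   `names`, `reference`, `lower`, `upper`, `positive`.
#' @examples
#' parameterSpace(c("a", "b"), c(1, 2), lower = 0)
#' @export
parameterSpace <- function(names, reference, lower = -Inf, upper = Inf,
                           positive = NULL) {
  names <- as.character(names)
  p <- length(names)
  if (anyDuplicated(names)) domainError("parameter names must be unique")
  reference <- as.numeric(reference)
  if (length(reference) != p)
    domainError("reference must have one value per parameter name")
  lower <- rep_len(as.numeric(lower), p)
  upper <- rep_len(as.numeric(upper), p)
  if (any(!is.finite(reference)))
    domainError("reference must be finite")
  if (any(reference <= lower | reference >= upper))
    domainError("reference must lie strictly inside every domain")
  if (is.null(positive)) positive <- reference > 0 & lower >= 0
  positive <- rep_len(as.logical(positive), p)
  structure(
    list(names = names, reference = setNames(reference, names),
         lower = setNames(lower, names), upper = setNames(upper, names),
         positive = setNames(positive, names)),
    class = "parameterSpace"
  )
}

#' @export
print.parameterSpace <- function(x, ...) {
  cat("Parameter space with", length(x$names), "parameters\n")
  print(data.frame(reference = x$reference, lower = x$lower,
                   upper = x$upper, positive = x$positive,
                   row.names = x$names))
  invisible(x)
}

## Is theta inside the (closed-with-tolerance) domain box?
inDomain <- function(space, theta) {
  all(is.finite(theta)) && all(theta > space$lower) && all(theta < space$upper)
}

checkTheta <- function(space, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != length(space$names))
    domainError(sprintf("theta has length %d, expected %d",
                        length(theta), length(space$names)))
  if (!inDomain(space, theta))
    domainError("theta lies outside the parameter domain box")
  setNames(theta, space$names)
}

#' Bijective parameter transforms to the real line
#'
#' Builds forward/backward maps between the natural parameter scale and
#' an unconstrained working scale used by the profile-likelihood
#' machinery. Mode `"log"` applies the natural logarithm to parameters
#' flagged positive (required for box-free profiling of positive
#' parameters); mode `"identity"` leaves all components untouched.
#' A per-parameter character vector mixes the two.
#'
#' @param space A [parameterSpace()].
#' @param mode `"identity"`, `"log"`, or a character vector with one of
#'   the two per parameter.
#' @return A list with functions `to` (natural -> working) and `from`
#'   (working -> natural), plus the per-parameter `mode` vector.
#' @examples
#' sp <- parameterSpace(c("a", "b"), c(0.051, 2), lower = c(0, -Inf))
#' tr <- parameterTransform(sp, c("log", "identity"))
#' tr$to(sp$reference)   # log(0.051), 2
#' @export
parameterTransform <- function(space, mode = "identity") {
  p <- length(space$names)
  mode <- rep_len(as.character(mode), p)
  if (!all(mode %in% c("identity", "log")))
    domainError("transform mode must be 'identity' or 'log'")
  if (any(mode == "log" & !space$positive))
    domainError("log transform requested for a parameter not flagged positive")
  if (any(mode == "log" & space$reference <= 0))
    domainError("log transform requires a positive reference")
  is_log <- mode == "log"
  to <- function(theta) {
    psi <- as.numeric(theta)
    psi[is_log] <- log(psi[is_log])
    setNames(psi, space$names)
  }
  from <- function(psi) {
    theta <- as.numeric(psi)
    theta[is_log] <- exp(theta[is_log])
    setNames(theta, space$names)
  }
  list(to = to, from = from, mode = setNames(mode, space$names))
}
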