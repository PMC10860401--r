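## Shared fixtures, all built in code.

## Linear-Gaussian toy model: observable at integer time t is the t-th
## row of A times theta. chi2 is exactly quadratic, so ordinary least
## squares provides closed forms for the estimate, its standard errors,
## the profile parabola and the Wald intervals -- the core correctness
## oracle for the profile/PLCI machinery.
linearModel <- function(A, theta0 = rep(1, ncol(A))) {
  p <- ncol(A)
  space <- parameterSpace(paste0("th", seq_len(p)), theta0, lower = -Inf)
  dynamicalModel(
    time = "discrete", space = space, x0 = c(x = 0),
    transition = function(t, state, theta, input) state,
    observation = function(t, state, theta, input) {
      c(y = if (t == 0) 0 else sum(A[t, ] * theta))
    },
    obs_names = "y", name = "linear-toy"
  )
}

linearProtocol <- function(A, sigma = 0.5) {
  observationProtocol(times = seq_len(nrow(A)), observed = "y",
                      noise = noiseAbsolute(sigma))
}

## Ordinary least squares oracle for the linear toy model
linearOLS <- function(A, y, sigma) {
  XtX <- crossprod(A)
  theta_hat <- drop(solve(XtX, crossprod(A, y)))
  se <- sigma * sqrt(diag(solve(XtX)))
  chi2min <- sum((y - drop(A %*% theta_hat))^2) / sigma^2
  list(theta = theta_hat, se = se, chi2min = chi2min)
}

## noise-free dataset with positive chi2 weights
noiselessDataset <- function(model, protocol, theta, sd_weight = 0.1) {
  traj <- simulateModel(model, theta,
                        times = pident:::simulationGrid(model, protocol))
  eta <- observe(traj, protocol)
  ds <- makeDataset(eta, rep(0, length(eta)), protocol, seed = 1,
                    theta = theta)
  ds$sd <- sd_weight
  ds
}

## Independent fixed-step classical RK4 integrator (oracle for the
## adaptive solver on the epidemic model)
rk4Epidemics <- function(theta, times, h = 1e-3, variant = "removal",
                         x0 = c(0, 0, 0)) {
  f <- function(t, y) epidemicsRHS(t, y, theta, variant = variant)
  out <- matrix(NA_real_, length(times), 3)
  y <- x0; t <- 0; k <- 1
  for (target in times) {
    while (t < target - 1e-12) {
      step <- min(h, target - t)
      k1 <- f(t, y); k2 <- f(t + step / 2, y + step / 2 * k1)
      k3 <- f(t + step / 2, y + step / 2 * k2); k4 <- f(t + step, y + step * k3)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[k, ] <- y; k <- k + 1
  }
  out
}

epiReference <- function() epidemicsReference()
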