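test_that("chi-square objective matches its definition and vanishes at the truth", {
  m <- epidemicsModel()
  pr <- epidemicsProtocol()
  ds <- noiselessDataset(m, pr, epiReference())
  obj <- chi2Objective(m, pr, ds)
  expect_equal(chi2(epiReference(), obj), 0, tolerance = 1e-12)
  ## single record: y = 1, model value 0, sigma = 0.5 -> chi2 = 4
  A <- matrix(0, 1, 1)
  toy <- linearModel(A, 1)
  toy_pr <- observationProtocol(1, "y")
  ds1 <- makeDataset(c(1), 0, toy_pr, seed = 1)
  ds1$sd <- 0.5
  expect_equal(chi2(3, chi2Objective(toy, toy_pr, ds1)), 4)
})

test_that("chi-square of a linear model is quadratic with Hessian 2 A' W A", {
  set.seed(2)
  A <- matrix(rnorm(15), 5, 3)
  sigma <- 0.4
  m <- linearModel(A, c(1, 1, 1))
  pr <- linearProtocol(A, sigma)
  ds <- simulateDataset(m, pr, theta = c(1, 2, -1), seed = 3)
  obj <- chi2Objective(m, pr, ds)
  fn <- function(th) chi2(th, obj)
  H <- stats::optimHess(c(0.5, 0.5, 0.5), fn)
  expect_equal(H, 2 * crossprod(A) / sigma^2, tolerance = 1e-4)
})

test_that("fits recover the least-squares solution and are deterministic", {
  set.seed(4)
  A <- matrix(rnorm(12), 6, 2)
  sigma <- 0.3
  m <- linearModel(A, c(1, 1))
  pr <- linearProtocol(A, sigma)
  ds <- simulateDataset(m, pr, theta = c(2, -1), seed = 8)
  obj <- chi2Objective(m, pr, ds)
  fit1 <- fitModel(obj, init = c(0.3, 0.3),
                   control = list(reltol = 1e-12, restarts = 2))
  fit2 <- fitModel(obj, init = c(0.3, 0.3),
                   control = list(reltol = 1e-12, restarts = 2))
  expect_identical(fit1$par, fit2$par)
  y <- ds$value[match(paste("y", 1:6), paste(ds$component, ds$time))]
  oracle <- linearOLS(A, y, sigma)
  expect_equal(unname(fit1$par), oracle$theta, tolerance = 1e-6)
  expect_equal(fit1$value, oracle$chi2min, tolerance = 1e-8)
  ## noise-free data fitted from the truth stays at the truth
  ds0 <- noiselessDataset(m, pr, c(2, -1))
  fit0 <- fitModel(chi2Objective(m, pr, ds0), init = c(2, -1))
  expect_equal(unname(fit0$par), c(2, -1), tolerance = 1e-6)
  expect_lt(fit0$value, 1e-12)
})

test_that("profiles of a one-parameter model reproduce the raw objective", {
  A <- matrix(c(1, 2, 3), 3, 1)
  m <- linearModel(A, 1)
  pr <- linearProtocol(A, 0.5)
  ds <- simulateDataset(m, pr, theta = 1.5, seed = 2)
  obj <- chi2Objective(m, pr, ds)
  prof <- profileLikelihood(obj, 1, box_radius = 5)
  direct <- vapply(prof$theta, function(v) chi2(v, obj), numeric(1))
  expect_equal(prof$chi2PL, direct, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(min(prof$chi2PL), prof$fit$value, tolerance = 1e-9)
})

test_that("linear-Gaussian profiles are parabolic and PLCIs match Wald intervals", {
  set.seed(5)
  A <- matrix(rnorm(16), 8, 2)
  sigma <- 0.25
  m <- linearModel(A, c(1, 1))
  pr <- linearProtocol(A, sigma)
  ds <- simulateDataset(m, pr, theta = c(1.5, -0.5), seed = 9)
  obj <- chi2Objective(m, pr, ds)
  y <- ds$value[match(paste("y", 1:8), paste(ds$component, ds$time))]
  oracle <- linearOLS(A, y, sigma)
  fit <- fitModel(obj, init = c(1, 1), control = list(reltol = 1e-13,
                                                      restarts = 2))
  for (i in 1:2) {
    prof <- profileLikelihood(obj, i, fit = fit, box_radius = 50)
    ## profile parabola: chi2min + (theta_i - theta_hat_i)^2 / se_i^2
    expected <- oracle$chi2min +
      (prof$theta - oracle$theta[i])^2 / oracle$se[i]^2
    keep <- expected < oracle$chi2min + 100
    expect_lt(max(abs(prof$chi2PL[keep] - expected[keep])), 1e-5)
    ## PLCI at 95%: theta_hat +- 1.96 se (Delta = 3.841), exact for a
    ## quadratic objective
    ci <- plci(obj, i, alpha = 0.95, profile = prof)
    z <- sqrt(qchisq(0.95, 1))
    expect_equal(unname(ci$lower), oracle$theta[i] - z * oracle$se[i],
                 tolerance = 1e-3)
    expect_equal(unname(ci$upper), oracle$theta[i] + z * oracle$se[i],
                 tolerance = 1e-3)
    ## intervals shrink towards a point as alpha -> 0 and nest with alpha
    tiny <- plci(obj, i, alpha = 0.01, profile = prof)
    expect_lt(tiny$upper - tiny$lower, 0.05 * (ci$upper - ci$lower))
    lad <- lapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(a)
      plci(obj, i, alpha = a, profile = prof))
    for (k in seq_len(length(lad) - 1)) {
      expect_lte(lad[[k + 1]]$lower, lad[[k]]$lower + 1e-9)
      expect_gte(lad[[k + 1]]$upper, lad[[k]]$upper - 1e-9)
    }
  }
})

test_that("parameters absent from the observation map are flagged nonidentifiable", {
  set.seed(6)
  A <- cbind(rnorm(6), 0)  # second parameter has no effect
  m <- linearModel(A, c(1, 1))
  pr <- linearProtocol(A, 0.5)
  ds <- simulateDataset(m, pr, theta = c(2, 1), seed = 4)
  obj <- chi2Objective(m, pr, ds)
  prof <- profileLikelihood(obj, 2, box_radius = 100)
  for (a in c(0.2, 0.95)) {
    ci <- plci(obj, 2, alpha = a, profile = prof)
    expect_false(any(ci$finite))
    expect_identical(unname(c(ci$lower, ci$upper)), c(-Inf, Inf))
  }
})

test_that("parameter transforms are bijective and leave the objective invariant", {
  sp <- parameterSpace(c("lambda0", "b"), c(0.051, 2), lower = c(0, -Inf),
                       positive = c(TRUE, FALSE))
  tr <- parameterTransform(sp, c("log", "identity"))
  expect_equal(tr$to(c(0.051, 2)), c(lambda0 = log(0.051), b = 2))
  expect_equal(tr$from(tr$to(c(0.051, 2))), c(lambda0 = 0.051, b = 2),
               tolerance = 1e-15)
  expect_error(parameterTransform(sp, c("log", "log")),
               class = "pident_domain_error")
  ## chi2 computed through a log-transformed objective matches the
  ## untransformed value at corresponding points
  m <- epidemicsModel()
  pr <- epidemicsProtocol()
  ds <- simulateDataset(m, pr, seed = 3)
  plain <- chi2Objective(m, pr, ds)
  logged <- chi2Objective(m, pr, ds, transform = "log")
  th <- epiReference() * 1.1
  expect_equal(chi2(th, plain), chi2(th, logged))
  fn <- pident:::workingChi2(logged)
  expect_equal(fn(log(th)), chi2(th, plain), tolerance = 1e-10)
})
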