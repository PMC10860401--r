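test_that("sensitivity entries match the analytic Jacobian of a linear output", {
  set.seed(1)
  A <- matrix(rnorm(18), 6, 3)
  theta0 <- c(1.5, -2, 0.7)
  m <- linearModel(A, theta0)
  pr <- observationProtocol(1:6, "y")
  dtheta <- c(2, 3, 4)
  S <- sensitivityMatrix(m, pr, dtheta = dtheta, scaling = "none")
  expected <- sweep(A, 2, dtheta, "*")
  expect_lt(max(abs(S$entries - expected) / pmax(abs(expected), 1e-8)), 1e-6)
  ## a parameter with no effect yields an all-zero column
  A0 <- cbind(A[, 1:2], 0)
  S0 <- sensitivityMatrix(linearModel(A0, theta0), pr, scaling = "none")
  expect_true(all(S0$entries[, 3] == 0))
  expect_identical(collinearityIndex(S0, 3), Inf)
})

test_that("central differences converge at second order (Richardson check)", {
  ## smooth nonlinear observables with a closed-form Jacobian
  coefs <- cbind(a = c(1, 0.3, -0.5, 2), b = c(0.2, 1, 0.4, -1),
                 c = c(0.1, -0.2, 1, 0.5))
  theta0 <- c(th1 = 1.2, th2 = 0.8)
  m <- dynamicalModel(
    time = "discrete",
    space = parameterSpace(names(theta0), theta0, lower = -Inf),
    x0 = c(x = 0),
    transition = function(t, state, theta, input) state,
    observation = function(t, state, theta, input) {
      if (t == 0) return(c(y = 0))
      cf <- coefs[t, ]
      c(y = cf[["a"]] * theta[1]^2 + cf[["b"]] * theta[1] * theta[2] +
          cf[["c"]] * theta[2]^3)
    }, obs_names = "y")
  pr <- observationProtocol(1:4, "y")
  exact <- cbind(2 * theta0[1] * coefs[, "a"] + theta0[2] * coefs[, "b"],
                 theta0[1] * coefs[, "b"] + 3 * theta0[2]^2 * coefs[, "c"])
  errAt <- function(h) {
    S <- sensitivityMatrix(m, pr, dtheta = c(1, 1), rel_step = h,
                           scaling = "none")
    max(abs(S$entries - exact))
  }
  ratio <- errAt(0.2) / errAt(0.1)
  expect_gt(ratio, 3)   # O(h^2): halving the step divides the error by ~4
  expect_lt(ratio, 5.5)
})

test_that("collinearity indices obey the closed forms and conventions", {
  ## orthogonal columns: gamma = 1
  expect_equal(collinearityIndex(diag(2), 1:2), 1)
  ## duplicated column: lambda_min = 0 convention gives Inf
  expect_identical(collinearityIndex(cbind(c(1, 2), c(1, 2)), 1:2), Inf)
  ## pair with cosine c: gamma = 1 / sqrt(1 - |c|); c = 0.96 gives 5
  M <- cbind(c(1, 0), c(0.96, sqrt(1 - 0.96^2)))
  expect_equal(collinearityIndex(M, 1:2), 5)
  ## random pairs against the eigen route, to 1e-10
  set.seed(7)
  for (r in 1:20) {
    P <- matrix(rnorm(12), 6, 2)
    cosang <- abs(sum(P[, 1] * P[, 2])) /
      sqrt(sum(P[, 1]^2) * sum(P[, 2]^2))
    expect_equal(collinearityIndex(P, 1:2), 1 / sqrt(1 - cosang),
                 tolerance = 1e-10)
  }
  ## singletons of nonzero columns are exactly 1
  S <- sensitivityMatrix(epidemicsModel(), epidemicsProtocol())
  for (j in 1:5) expect_equal(collinearityIndex(S, j), 1)
  expect_error(collinearityIndex(S, integer(0)),
               class = "pident_domain_error")
  expect_error(collinearityIndex(S, "nope"), class = "pident_domain_error")
})

test_that("indices are invariant to uncertainty-range rescaling and monotone under inclusion", {
  m <- epidemicsModel()
  pr <- epidemicsProtocol()
  S1 <- sensitivityMatrix(m, pr)
  set.seed(3)
  scales <- exp(rnorm(5))
  S2 <- S1
  S2$entries <- sweep(S1$entries, 2, scales, "*")  # exact column rescaling
  all1 <- subsetCollinearity(S1, 2, 5)
  all2 <- subsetCollinearity(S2, 2, 5)
  expect_equal(all1$gamma[order(all1$subset)], all2$gamma[order(all2$subset)],
               tolerance = 1e-12)
  ## dtheta really rescales columns linearly
  S3 <- sensitivityMatrix(m, pr, dtheta = scales * S1$dtheta)
  expect_equal(S3$entries, sweep(S1$entries, 2, scales, "*"),
               tolerance = 1e-12)
  ## gamma >= 1 and subset monotonicity (Cauchy interlacing) on the
  ## epidemic sensitivity matrix and on random matrices
  checkMonotone <- function(entries) {
    p <- ncol(entries)
    subs <- unlist(lapply(1:p, function(k) combn(p, k, simplify = FALSE)),
                   recursive = FALSE)
    gam <- vapply(subs, function(K) pident:::gammaOf(entries, K), numeric(1))
    names(gam) <- vapply(subs, paste, "", collapse = ",")
    expect_true(all(gam >= 1 - 1e-12))
    for (s in seq_along(subs)) {
      K <- subs[[s]]
      if (length(K) == 1) next
      for (drop in seq_along(K)) {
        sub_key <- paste(K[-drop], collapse = ",")
        expect_lte(gam[[sub_key]], gam[[s]] + 1e-9)
      }
    }
  }
  checkMonotone(S1$entries)
  set.seed(11)
  for (r in 1:3) checkMonotone(matrix(rnorm(40), 8, 5))
})

test_that("subset enumeration reports sorted tables and honors the cap", {
  S <- sensitivityMatrix(epidemicsModel(), epidemicsProtocol())
  cs <- subsetCollinearity(S, 2, 5)
  expect_equal(nrow(cs), sum(choose(5, 2:5)))
  expect_true(all(diff(cs$gamma) <= 0))
  expect_equal(cs$compensation, compensationPercent(cs$gamma))
  expect_error(subsetCollinearity(S, 2, 5, cap = 3),
               class = "pident_cap_error")
  ## row-scaling perturbation moves indices continuously, not abruptly
  S_bump <- S
  S_bump$entries[1, ] <- S$entries[1, ] * 1.01
  cs_bump <- subsetCollinearity(S_bump, 2, 5)
  expect_lt(max(abs(cs_bump$gamma[order(cs_bump$subset)] -
                      cs$gamma[order(cs$subset)]) /
                  cs$gamma[order(cs$subset)]), 0.2)
})

test_that("model variant and row scaling drive the published compensation structure", {
  pr <- epidemicsProtocol()
  ## without the removal term the death rate cannot shape the infected
  ## curve, so the (mu, d) compensation is structurally weak
  S_printed <- sensitivityMatrix(epidemicsModel(variant = "as-printed"), pr)
  expect_lt(collinearityIndex(S_printed, c("mu", "d")), 5)
  S_removal <- sensitivityMatrix(epidemicsModel(variant = "removal"), pr)
  expect_gt(collinearityIndex(S_removal, c("mu", "d")), 20)
  ## per-component scaling amplifies the small infected counts and
  ## pushes the subset maximum past 50; the global constant stays below
  m <- epidemicsModel()
  comp_max <- max(subsetCollinearity(
    sensitivityMatrix(m, pr, scaling = "component"), 2, 5)$gamma)
  glob_max <- max(subsetCollinearity(
    sensitivityMatrix(m, pr, scaling = "global"), 2, 5)$gamma)
  expect_gt(comp_max, 50)
  expect_lte(glob_max, 50)
  ## the infection-parameter pairs agree exactly under both scalings
  for (K in list(c("lambda0", "mu"), c("lambda0", "d"), c("mu", "d")))
    expect_equal(
      collinearityIndex(sensitivityMatrix(m, pr, scaling = "component"), K),
      collinearityIndex(sensitivityMatrix(m, pr, scaling = "global"), K),
      tolerance = 1e-9)
})

test_that("compensation percentages follow (1 - 1/gamma) * 100", {
  expect_equal(round(compensationPercent(15)), 93)
  expect_equal(compensationPercent(1), 0)
  expect_equal(compensationPercent(Inf), 100)
  expect_equal(compensationPercent(2), 50)
  expect_error(compensationPercent(0.5), class = "pident_domain_error")
})

test_that("prior-averaged indices degenerate correctly and scale like Monte Carlo", {
  m <- epidemicsModel()
  pr <- epidemicsProtocol()
  pairs <- list(c("mu", "d"), c("b", "kappa"))
  ## degenerate prior equals the local index exactly
  local <- sensitivityMatrix(m, pr)
  deg <- meanCollinearity(m, pr, subsets = pairs, n_samples = 3, seed = 1,
                          prior_log_sd = 0)
  expect_equal(deg$mean_gamma,
               vapply(pairs, function(K) collinearityIndex(local, K),
                      numeric(1)))
  ## same seed twice gives the identical table
  a <- meanCollinearity(m, pr, subsets = pairs, n_samples = 8, seed = 5,
                        prior_log_sd = 0.3)
  b <- meanCollinearity(m, pr, subsets = pairs, n_samples = 8, seed = 5,
                        prior_log_sd = 0.3)
  expect_identical(a, b)
  ## quadrupling the sample size roughly halves the Monte-Carlo se
  small <- meanCollinearity(m, pr, subsets = pairs[1], n_samples = 30,
                            seed = 2, prior_log_sd = 0.3)
  big <- meanCollinearity(m, pr, subsets = pairs[1], n_samples = 120,
                          seed = 2, prior_log_sd = 0.3)
  expect_gt(small$mc_se[1] / big$mc_se[1], 1.2)
  expect_lt(small$mc_se[1] / big$mc_se[1], 3.5)
})
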