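test_that("log-normal CDF honors its median, support and quadrature oracle", {
  expect_equal(lognormalCDF(550, 550, 950), 0.5)
  expect_equal(lognormalCDF(550, 550, 950, convention = "sdlog"), 0.5)
  expect_equal(lognormalCDF(0, 500, 100), 0)
  expect_equal(lognormalCDF(-3, 500, 100), 0)
  x <- seq(0, 3000, by = 50)
  expect_true(all(diff(lognormalCDF(x, 550, 950)) >= 0))
  ## quadrature of the chosen density (variate-sd convention)
  v <- (1 + sqrt(1 + 4 * (100 / 500)^2)) / 2
  s <- sqrt(log(v))
  quad <- integrate(function(u) stats::dlnorm(u, log(500), s), 0, 700,
                    rel.tol = 1e-12)$value
  expect_equal(lognormalCDF(700, 500, 100), quad, tolerance = 1e-8)
  expect_error(lognormalCDF(1, -1, 1), class = "pident_domain_error")
  expect_error(lognormalCDF(1, 1, 0), class = "pident_domain_error")
})

test_that("epidemic vector field matches the printed equations and variants", {
  theta <- epiReference()
  ## empty plot: production only, at rate b*kappa = 1.177 * 4.876
  d0 <- epidemicsRHS(3, c(0, 0, 0), theta)
  expect_equal(d0, c(1.177 * 4.876, 0, 0))
  ## as printed, no infection force means dI/dt = 0 for any state
  theta0 <- theta; theta0["lambda0"] <- 0
  expect_equal(epidemicsRHS(5, c(2, 1, 0.5), theta0)[2], 0)
  ## as printed, S = 0 means dI/dt = 0 regardless of t
  expect_equal(epidemicsRHS(7, c(0, 1, 0.5), theta)[2], 0)
  ## removal variant subtracts d*I
  dr <- epidemicsRHS(7, c(0, 1, 0.5), theta, variant = "removal")
  expect_equal(dr[2], -theta[["d"]] * 1, ignore_attr = TRUE)
  expect_equal(dr[3], theta[["d"]] * 1, ignore_attr = TRUE)
})

test_that("epidemic trajectories keep I and R non-decreasing and N consistent", {
  for (variant in c("removal", "as-printed")) {
    m <- epidemicsModel(variant = variant)
    tr <- simulateModel(m, times = seq(0, 12, 0.5))
    ## R accumulates and I stays non-negative in both variants; the
    ## cumulative-infection (as-printed) I is additionally monotone
    expect_true(all(diff(tr$states[, "R"]) > -1e-10))
    expect_true(all(tr$states[, "I"] > -1e-10))
    if (variant == "as-printed")
      expect_true(all(diff(tr$states[, "I"]) > -1e-10))
    expect_equal(unname(tr$observables[, "N"]), unname(rowSums(tr$states)))
  }
  ## under the removal variant the total decouples: N(t) = kappa (1 - e^{-bt})
  m <- epidemicsModel()
  tr <- simulateModel(m, times = seq(0, 12, 2))
  th <- epiReference()
  expect_equal(unname(rowSums(tr$states)),
               unname(th[["kappa"]] * (1 - exp(-th[["b"]] * tr$times))),
               tolerance = 1e-6)
})

test_that("LNAS conserves mass and keeps green biomass below total leaf mass", {
  w <- generateWeather(151, seed = 42)
  m <- lnasModel(weather = w)
  tr <- simulateModel(m, times = 0:150)
  st <- tr$states
  ## mass balance: Ql + Qr equals the cumulative production bookkeeping
  expect_lt(max(abs(st[, "Ql"] + st[, "Qr"] - st[, "cum"]) /
                  pmax(st[, "cum"], 1e-12)), 1e-10)
  ## senescence fraction in [0,1]: green leaf mass never exceeds leaf mass
  expect_true(all(tr$observables[, "Qg"] <= st[, "Ql"] + 1e-12))
  expect_true(all(is.finite(st)))
  ## yield is non-decreasing and ends up sigmoidal-positive
  expect_true(all(diff(st[, "Qr"]) > -1e-12))
  expect_gt(st[151, "Qr"], 100)
})

test_that("LNAS production stops without radiation and thermal time never decreases", {
  w <- generateWeather(30, seed = 1)
  w$PAR <- 0
  m <- lnasModel(weather = w)
  tr <- simulateModel(m, times = 0:29)
  ## day 0 releases the seed mass; nothing accumulates afterwards
  expect_equal(unname(diff(tr$states[-1, "Ql"])), rep(0, 28))
  expect_equal(unname(diff(tr$states[-1, "Qr"])), rep(0, 28))

  st <- c(tau = 100, Ql = 5, Qr = 2, cum = 7)
  out <- lnasStep(st, lnasParameters(), lnasConstants(Tb = 5), T_t = 2,
                  PAR_t = 3)
  expect_equal(out$state[["tau"]], 100)  # max(0, T - Tb) clamps at 0
  ## allocation fraction: gamma0 at tau = 0, gammaf as tau -> Inf
  p <- lnasParameters()
  s0 <- lnasStep(c(tau = 0, Ql = 5, Qr = 0, cum = 5), p, lnasConstants(),
                 T_t = 10, PAR_t = 4)
  expect_equal((s0$state[["Ql"]] - 5) / s0$Q, p[["gamma0"]])
  ## push senescence far out so the allocation limit is not confounded
  pLate <- lnasParameters(mu_s = 1e12)
  sInf <- lnasStep(c(tau = 1e9, Ql = 5, Qr = 0, cum = 5), pLate,
                   lnasConstants(), T_t = 10, PAR_t = 4)
  expect_equal((sInf$state[["Ql"]] - 5) / sInf$Q, pLate[["gammaf"]],
               tolerance = 1e-6)
  ## interception never exceeds the 95% absorption ceiling
  expect_lt(s0$Q / (p[["RUE"]] * 4), 0.95)
})

test_that("doubling radiation-use efficiency never lowers final yield", {
  w <- generateWeather(151, seed = 7)
  base <- lnasParameters()
  double <- lnasParameters(RUE = 2 * base[["RUE"]])
  y1 <- simulateModel(lnasModel(base, weather = w), times = 0:150)
  y2 <- simulateModel(lnasModel(double, weather = w),
                      theta = double, times = 0:150)
  expect_gte(y2$states[151, "Qr"], y1$states[151, "Qr"])
})

test_that("synthetic weather is reproducible, non-negative and sinusoidal without noise", {
  a <- generateWeather(100, seed = 3)
  b <- generateWeather(100, seed = 3)
  expect_identical(a, b)
  long <- generateWeather(10000, seed = 11)
  expect_true(all(long$PAR >= 0))
  pure <- generateWeather(5, seed = 1,
                          profile = list(t_sd = 0, p_sd = 0))
  expect_equal(pure$T[1], 16 + 6 * sin(-2 * pi * 80 / 365 + pi / 2))
  ## weather shorter than the horizon is an input error
  m <- lnasModel(weather = generateWeather(10, seed = 1))
  expect_error(simulateModel(m, times = 0:20),
               class = "pident_simulation_error")
})
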