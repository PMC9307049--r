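test_that("closed form reproduces boundary and characteristic values", {
  # no tip source: everything stays zero
  s0 <- solveGrowthClosedForm(growthParams(k = 0, v = 1), 0:3, 0:3)
  expect_true(all(tipDensity(s0) == 0) && all(lengthDensity(s0) == 0))

  # boundary value k/v and linear accumulation at the interface
  s1 <- solveGrowthClosedForm(growthParams(k = 1, v = 1), c(0, 0.5), c(0, 2))
  expect_equal(tipDensity(s1)[1, 2], 1)
  expect_equal(lengthDensity(s1)[1, 2], 2)

  # characteristic quadrature oracle at (x = 1, t = 3)
  s2 <- solveGrowthClosedForm(growthParams(k = 2, v = 1, b_branch = 0.5,
                                           d = 0.1), c(0, 1), c(0, 3))
  expect_equal(tipDensity(s2)[2, 2], 2 * exp(0.5), tolerance = 1e-12)
  expect_equal(lengthDensity(s2)[2, 2],
               oracle_rho(k = 2, v = 1, b = 0.5, d = 0.1, x = 1, t = 3),
               tolerance = 1e-9)
})

test_that("fields vanish exactly ahead of the colonisation front", {
  set.seed(11)
  for (i in 1:20) {
    p <- growthParams(k = runif(1, 0, 1e-3), v = 10^runif(1, -6, -4),
                      b_branch = runif(1, 0, 1e-5), d = runif(1, 0, 1e-5))
    xg <- sort(runif(8, 0, 5)); tg <- sort(runif(6, 0, 3e6))
    s <- solveGrowthClosedForm(p, xg, tg)
    front <- outer(xg, tg, function(x, t) x >= p@v * t)
    expect_true(all(lengthDensity(s)[front] == 0))
    expect_true(all(tipDensity(s)[front] == 0))
    if (p@k > 0) {
      expect_true(all(lengthDensity(s)[!front & outer(xg, tg,
        function(x, t) t > x / p@v)] > 0))
    }
  }
})

test_that("rho is non-decreasing in time when d = 0, and integrates to k v t^2 / 2 when b = d = 0", {
  p <- growthParams(k = 3e-4, v = 2e-5, b_branch = 4e-6, d = 0)
  s <- solveGrowthClosedForm(p, seq(0, 4.5, length.out = 40),
                             seq(0, 3e6, length.out = 30))
  expect_true(all(diff(t(lengthDensity(s))) >= -1e-15))

  p2 <- growthParams(k = 1, v = 1, b_branch = 0, d = 0)
  t_end <- 2
  xg <- seq(0, 2.5, length.out = 4001)
  s2 <- solveGrowthClosedForm(p2, xg, c(0, t_end))
  total <- pracma::trapz(xg, lengthDensity(s2)[, 2])
  expect_equal(total, p2@k * p2@v * t_end^2 / 2, tolerance = 1e-5)
})

test_that("grid and parameter validation errors are specific", {
  expect_error(growthParams(k = 1, v = 0), class = "mycouptake_invalid_parameter")
  expect_error(growthParams(k = 1, v = -2), class = "mycouptake_invalid_parameter")
  p <- growthParams(k = 1, v = 1)
  expect_error(solveGrowthClosedForm(p, c(1, 0.5), 0:1),
               class = "mycouptake_invalid_grid")
  expect_error(solveGrowthClosedForm(p, c(0, 1), c(2, 1)),
               class = "mycouptake_invalid_grid")
})

test_that("upwind solver matches the closed form and keeps the front exact", {
  p <- growthParams(k = 2, v = 1, b_branch = 0.5, d = 0.1)
  xg <- seq(0, 2.9, length.out = 200)
  tg <- seq(0, 3, length.out = 200)
  num <- solveGrowthNumeric(p, xg, tg)
  cf <- solveGrowthClosedForm(p, xg, tg)
  err <- max(abs(lengthDensity(num) - lengthDensity(cf))) /
    max(lengthDensity(cf))
  expect_lt(err, 0.02)

  # exactly zero ahead of the front (upwind with zero inflow)
  front <- outer(xg, tg, function(x, t) x >= p@v * t)
  expect_true(all(lengthDensity(num)[front] == 0))
  expect_true(all(tipDensity(num)[front] == 0))

  # zero source stays identically zero
  num0 <- solveGrowthNumeric(growthParams(k = 0, v = 1), xg, tg)
  expect_true(all(lengthDensity(num0) == 0))

  expect_error(solveGrowthNumeric(p, xg, tg, cfl_fraction = 0),
               class = "mycouptake_invalid_parameter")
})

test_that("evaluateAt agrees with the solver and handles t = 0", {
  p <- growthParams(k = 1.02e-4, v = 2.06e-5, b_branch = 5.45e-6)
  h <- c(1.35, 2.85, 4.35)
  tt <- c(2, 4) * 7 * 24 * 3600
  obs <- observationSet(rep(h, 2), rep(tt, each = 3), rep(1, 6), rep(0, 6))
  pred <- evaluateAt(p, obs)
  expect_length(pred, 6L)
  expect_true(all(is.finite(pred)) && all(pred >= 0))
  sol <- solveGrowthClosedForm(p, h, tt)
  expect_equal(pred, as.vector(lengthDensity(sol)[cbind(rep(1:3, 2),
                                                        rep(1:2, each = 3))]),
               tolerance = 1e-12)

  obs0 <- observationSet(1, 0, 1, 0)
  expect_warning(p0 <- evaluateAt(p, obs0), "zero initial condition")
  expect_identical(p0, 0)
})

test_that("observation sets and growth solutions round-trip through CSV", {
  obs <- observationSet(c(1.35, 2.85), c(1e6, 1e6), c("a", "b"), c(3.2, 4.1),
                        sd_cm2 = c(0.2, 0.4))
  f <- withr::local_tempfile(fileext = ".csv")
  writeObservationSet(obs, f)
  back <- readObservationSet(f)
  expect_equal(records(back)$rho_cm2, c(3.2, 4.1))
  expect_equal(records(back)$sd_cm2, c(0.2, 0.4))

  sol <- solveGrowthClosedForm(growthParams(k = 1, v = 1, b_branch = 0.1),
                               c(0, 1), c(0, 1, 2))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeGrowthSolution(sol, f2)
  tab <- read.csv(f2)
  expect_equal(nrow(tab), 6L)
  expect_equal(matrix(tab$rho, 2, 3), lengthDensity(sol), ignore_attr = TRUE)
})
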