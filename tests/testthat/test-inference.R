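dense_obs <- function(truth, level = 0, seed = 3L) {
  genLengthDensityObs(truth, positions_cm = seq(0.4, 4.4, length.out = 10),
                      times_s = seq(1, 5) * 7 * 24 * 3600, replicates = 1L,
                      noise = list(type = "lognormal", level = level),
                      seed = seed)
}

test_that("R^2 matches hand arithmetic and guards degenerate input", {
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(1, 2, 3)
  expect_equal(rSquared(rep(mean(obs), 3), obs), 0)
  expect_equal(rSquared(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_error(rSquared(c(1, 2), c(5, 5)), class = "mycouptake_degenerate_data")
  expect_error(rSquared(1, 1), class = "mycouptake_invalid_parameter")
})

test_that("noise-free dense designs recover the growth kinetics to 0.1%", {
  truth <- growthParams(k = 1.02e-4, v = 2.06e-5, b_branch = 5.45e-6)
  f <- fitGrowth(dense_obs(truth), n_starts = 8L, seed = 7L)
  est <- estimates(f)
  tv <- c(k = truth@k, v = truth@v, b_branch = truth@b_branch)
  expect_true(all(abs(est[names(tv)] - tv) / tv < 1e-3))
  expect_equal(f@r2, 1, tolerance = 1e-9)
  expect_true(f@converged)
  expect_identical(est[["d"]], 0)
})

test_that("fits are deterministic given (obs, bounds, seed, n_starts)", {
  truth <- growthParams(k = 1.02e-4, v = 2.06e-5, b_branch = 5.45e-6)
  obs <- dense_obs(truth, level = 0.1, seed = 5L)
  f1 <- fitGrowth(obs, n_starts = 6L, seed = 42L)
  f2 <- fitGrowth(obs, n_starts = 6L, seed = 42L)
  expect_identical(estimates(f1), estimates(f2))
  expect_identical(f1@objective, f2@objective)
})

test_that("the sparse compartment design flags weak identifiability with d free", {
  truth <- growthParams(k = 1.02e-4, v = 2.06e-5, b_branch = 5.45e-6)
  obs <- genLengthDensityObs(truth, noise = list(type = "lognormal", level = 0),
                             replicates = 1L, seed = 1L)
  f <- fitGrowth(obs, fix_d = FALSE, n_starts = 8L, seed = 1L)
  expect_true(isTRUE(f@diagnostics$identifiability_warning))
})

test_that("degenerate observation sets raise specific errors", {
  truth <- growthParams(k = 1e-4, v = 2e-5)
  zero <- observationSet(c(1, 2, 3, 4), rep(1e6, 4), 1, rep(0, 4))
  expect_error(fitGrowth(zero), class = "mycouptake_degenerate_data")
  tiny <- observationSet(c(1, 2), c(1e6, 1e6), 1, c(1, 2))
  expect_error(fitGrowth(tiny), class = "mycouptake_degenerate_data")
})

test_that("replicate aggregation reports mean and sample SD", {
  truth <- growthParams(k = 1.02e-4, v = 2.06e-5, b_branch = 5.45e-6)
  obs <- genLengthDensityObs(truth, positions_cm = seq(0.4, 4.4, length.out = 6),
                             times_s = c(2, 4) * 7 * 24 * 3600,
                             replicates = 2L,
                             noise = list(type = "lognormal", level = 0.05),
                             seed = 2L)
  fits <- fitGrowthReplicates(obs, n_starts = 6L, seed = 1L)
  expect_named(fits, c("1", "2"))
  agg <- aggregateReplicates(fits)
  expect_equal(nrow(agg@replicates), 2L)
  expect_true(all(agg@sd[c("k", "v", "b_branch")] >= 0))

  # hand check of the mean +/- sample SD contract
  fk <- fits
  fk[[1]]@estimates["k"] <- 1; fk[[2]]@estimates["k"] <- 3
  agg2 <- aggregateReplicates(fk)
  expect_equal(unname(agg2@mean["k"]), 2)
  expect_equal(unname(agg2@sd["k"]), sqrt(2), tolerance = 1e-12)
  agg3 <- aggregateReplicates(list(fits[[1]], fits[[1]]))
  expect_true(all(agg3@sd == 0))

  expect_match(formatMeanSD(4.66e-4, 1.758e-4), "4.66 x 10-4")
  expect_match(formatMeanSD(4.66e-4, 1.758e-4), "1.76 x 10-4")
})

test_that("estimator spread shrinks as the design densifies", {
  truth <- growthParams(k = 1.02e-4, v = 2.06e-5, b_branch = 5.45e-6)
  sd_k <- vapply(c(6L, 24L), function(npos) {
    est <- vapply(1:15, function(s) {
      obs <- genLengthDensityObs(truth,
        positions_cm = seq(0.4, 4.4, length.out = npos),
        times_s = c(2, 4) * 7 * 24 * 3600, replicates = 1L,
        noise = list(type = "lognormal", level = 0.1), seed = 100L + s)
      estimates(fitGrowth(obs, n_starts = 4L, seed = s))[["k"]]
    }, numeric(1))
    sd(est)
  }, numeric(1))
  expect_gt(sd_k[1L], sd_k[2L])
})

test_that("lambda_h is recovered from noise-free profiles and scales with 1/r_m", {
  up <- uptakeParams(lambda_h = 3.26e-6)
  xg <- seq(0, 4.5, length.out = 121)
  pr <- genPProfile(up, 50, noise_sd = 0, x_grid = xg, nt = 25L, seed = 1L)
  f <- fitUptake(pr$profile, 50, up, t_final = 4 * 7 * 24 * 3600,
                 x_grid = xg, nt = 25L)
  lam <- estimates(f)[["lambda_h"]]
  expect_lt(abs(lam - 3.26e-6) / 3.26e-6, 0.01)
  expect_gt(f@r2, 0.999)
  expect_identical(f@diagnostics$r_m, up@r_m)

  # only the product r_m * lambda_h is identified
  up2 <- uptakeParams(lambda_h = 3.26e-6, r_m = 2 * up@r_m)
  f2 <- fitUptake(pr$profile, 50, up2, t_final = 4 * 7 * 24 * 3600,
                  x_grid = xg, nt = 25L)
  expect_equal(estimates(f2)[["lambda_h"]] / lam, 0.5, tolerance = 1e-3)
})

test_that("uptake fitting handles no-signal and unidentifiable cases", {
  up <- uptakeParams()
  flat <- data.frame(x_cm = seq(0.1, 4.3, length.out = 20), c_rel = 1)
  f <- fitUptake(flat, 50, up, t_final = 1e6,
                 x_grid = seq(0, 4.5, length.out = 91), nt = 15L)
  expect_identical(estimates(f)[["lambda_h"]], 0)

  above <- data.frame(x_cm = seq(0.1, 4.3, length.out = 20), c_rel = 1.2)
  expect_warning(fitUptake(above, 50, up, t_final = 1e6,
                           x_grid = seq(0, 4.5, length.out = 91), nt = 15L),
                 "no depletion")

  expect_error(fitUptake(flat, 0, up, t_final = 1e6),
               class = "mycouptake_unidentifiable")
})
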