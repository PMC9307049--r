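test_that("noise-free length densities equal the model and seeds reproduce", {
  gp <- growthParams(k = 1.02e-4, v = 2.06e-5, b_branch = 5.45e-6)
  obs <- genLengthDensityObs(gp, noise = list(type = "lognormal", level = 0),
                             seed = 1L)
  expect_equal(records(obs)$rho_cm2, evaluateAt(gp, obs), tolerance = 1e-12)
  expect_named(syntheticTruth(obs)$params, c("k", "v", "b_branch", "d"))

  o1 <- genLengthDensityObs(gp, seed = 7L)
  o2 <- genLengthDensityObs(gp, seed = 7L)
  expect_identical(records(o1), records(o2))
  o3 <- genLengthDensityObs(gp, seed = 8L)
  expect_false(identical(records(o1)$rho_cm2, records(o3)$rho_cm2))
})

test_that("multiplicative noise has the stated coefficient of variation", {
  gp <- growthParams(k = 1e-4, v = 2e-5, b_branch = 5e-6)
  obs <- genLengthDensityObs(gp,
    positions_cm = seq(0.5, 4.4, length.out = 10),
    times_s = seq(1, 10) * 6e5, replicates = 100L,
    noise = list(type = "lognormal", level = 0.1), seed = 12L)
  mu <- evaluateAt(gp, obs)
  mult <- records(obs)$rho_cm2 / mu
  cv <- sd(mult) / mean(mult)
  expect_gt(cv, 0.095); expect_lt(cv, 0.105)
})

test_that("deterministic straight skeletons carry their planted geometry", {
  sk <- genSkeleton(process = list(step_um = 8, persistence = 1,
                                   branch_prob = 0, stop_prob = 0),
                    n_tips = 3L, seed = 2L)
  g <- voxelSkeletonToGraph(sk$voxels, sk$voxel_size_um)
  m <- computeMetrics(g, c(1, 0, 0), 1e6)
  expect_true(all(m@tortuosity == 1))
  expect_true(all(m@angle_deg == 0))      # launch along the midline
  expect_equal(m@total_length_um, sum(sk$truth$branch_length_um),
               tolerance = 0.05)
})

test_that("voxelised skeleton metrics track the polyline truth", {
  for (s in 1:3) {
    sk <- genSkeleton(preset = "control", seed = s)
    g <- voxelSkeletonToGraph(sk$voxels, sk$voxel_size_um)
    truth_len <- sum(sk$truth$branch_length_um)
    expect_equal(sum(g@branch_length), truth_len, tolerance = 0.10)
  }
  s1 <- genSkeleton(preset = "inoculated", seed = 5L)
  s2 <- genSkeleton(preset = "inoculated", seed = 5L)
  expect_identical(s1$voxels, s2$voxels)
  expect_error(genSkeleton(domain = list(radius_um = -1, length_um = 10)),
               class = "mycouptake_invalid_parameter")
})

test_that("xrf maps plant recoverable phases and reproduce under one seed", {
  m1 <- genXRFMaps(seed = 4L)
  m2 <- genXRFMaps(seed = 4L)
  expect_identical(m1@elements, m2@elements)
  tr <- syntheticTruth(m1)
  expect_identical(classifyPhases(m1, 1000, 1e4), tr$phase)
  expect_true(all(tr$distance_um >= 0))
  # zero coupling: no planted P contrast signal in the field construction
  m0 <- genXRFMaps(coupling = list(profile = "exp", a_P = 0, a_Al = 0,
                                   ell_um = 60, close_um = 50), seed = 4L)
  tr0 <- syntheticTruth(m0)
  expect_equal(tr0$coupling$a_P, 0)
})

test_that("xanes generator honours weights and seed contracts", {
  pure <- genXANES(weights = c(thiol = 1, sulfonate = 0, sulfate = 0),
                   snr = Inf, seed = 1L)
  expect_equal(pure$mixture@intensity, pure$standards$thiol@intensity,
               tolerance = 1e-12)
  g1 <- genXANES(seed = 3L); g2 <- genXANES(seed = 3L)
  expect_identical(g1$mixture@intensity, g2$mixture@intensity)
  expect_error(genXANES(weights = c(thiol = 0.5, sulfonate = 0.2,
                                    sulfate = 0.2)),
               class = "mycouptake_invalid_parameter")
})

test_that("phosphorus profiles are flat without sinks and reproducible", {
  up0 <- uptakeParams(lambda_h = 0, F_max = 0)
  pr <- genPProfile(up0, 50, noise_sd = 0,
                    x_grid = seq(0, 4.5, length.out = 91), nt = 10L, seed = 1L)
  expect_equal(pr$profile$c_rel, rep(1, nrow(pr$profile)), tolerance = 1e-12)

  up <- uptakeParams(lambda_h = 3.26e-6)
  p1 <- genPProfile(up, 50, x_grid = seq(0, 4.5, length.out = 91), nt = 10L,
                    seed = 2L)
  p2 <- genPProfile(up, 50, x_grid = seq(0, 4.5, length.out = 91), nt = 10L,
                    seed = 2L)
  expect_identical(p1$profile, p2$profile)
  expect_equal(p1$truth$lambda_h, 3.26e-6)
})
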