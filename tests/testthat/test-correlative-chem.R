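test_that("distance transform is exact for single sources and random masks", {
  m <- array(FALSE, c(9, 9, 9)); m[1, 1, 1] <- TRUE
  d <- distanceTransform3D(m, voxel_size = 1.6)
  ijk <- as.matrix(expand.grid(0:8, 0:8, 0:8))
  expect_equal(as.vector(d), 1.6 * sqrt(rowSums(ijk^2)), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    mk <- array(runif(20^3) < 0.02, c(20, 20, 20))
    if (!any(mk)) next
    expect_lt(max(abs(distanceTransform3D(mk, 1.7) - oracle_edt(mk, 1.7))),
              1e-9)
  }

  expect_equal(max(distanceTransform3D(array(1, c(5, 5, 5)), 2)), 0)
  expect_error(distanceTransform3D(array(0, c(4, 4, 4)), 1),
               class = "mycouptake_empty_mask")
})

test_that("phase classification recovers planted geometry and edge cases", {
  map <- genXRFMaps(seed = 2)
  tr <- syntheticTruth(map)
  ph <- classifyPhases(map, air_threshold_total = 1000, si_threshold = 1e4)
  expect_identical(ph, tr$phase)

  zero <- xrfMap(list(P = matrix(0, 4, 4), S = matrix(0, 4, 4),
                      Al = matrix(0, 4, 4), Si = matrix(0, 4, 4)),
                 pixel_size_um = 5)
  expect_true(all(classifyPhases(zero, 10, 10) == "air"))

  hi_si <- xrfMap(list(P = matrix(100, 4, 4), Si = matrix(1e5, 4, 4)),
                  pixel_size_um = 5)
  expect_true(all(classifyPhases(hi_si, 10, 10) == "primary"))
})

test_that("distance classes apply the inclusive/exclusive tie rules", {
  d <- matrix(c(49.9, 50, 125, 200, 200.01, 250), 2, 3)
  cl <- distanceClasses(d)
  expect_identical(as.vector(cl),
                   c("close", "close", "neither", "neither", "far", "far"))
  expect_error(distanceClasses(d, close_um = 300, far_um = 200),
               class = "mycouptake_invalid_parameter")
  expect_warning(distanceClasses(matrix(300, 3, 3)), "close .* empty")
})

test_that("class statistics degenerate to zero for identical samples and normalise histograms", {
  vals <- matrix(rep(c(1000, 2000, 3000, 4000, 5000), 20), 10, 10)
  map <- xrfMap(list(P = vals, Si = matrix(0, 10, 10)), pixel_size_um = 5)
  phases <- matrix("mixed", 10, 10)
  classes <- matrix(rep(c("close", "far"), each = 50), 10, 10)
  # rows alternate values identically in both halves
  cs <- classStatistics(map, phases, classes, "P", bin_width = 500)
  expect_equal(unname(cs$t_test$statistic), 0)
  expect_equal(unname(cs$ks_test$statistic), 0)
  expect_equal(sum(cs$histograms$close$prob), 1)
  expect_equal(sum(cs$histograms$far$prob), 1)

  classes2 <- matrix("far", 10, 10); classes2[1, 1] <- "close"
  expect_error(classStatistics(map, phases, classes2, "P"),
               class = "mycouptake_empty_class")
})

test_that("shuffled distance labels give uniform p-values", {
  map <- genXRFMaps(shape_px = c(80L, 80L),
                    coupling = list(profile = "exp", a_P = 0, a_Al = 0,
                                    ell_um = 60, close_um = 50), seed = 8)
  tr <- syntheticTruth(map)
  ph <- classifyPhases(map, 1000, 1e4)
  cl <- distanceClasses(tr$distance_um)
  keep <- ph == "mixed" & cl != "neither"
  v <- map@elements$P[keep]
  lab <- cl[keep]
  set.seed(99)
  pvals <- replicate(300, {
    sl <- sample(lab)
    stats::t.test(v[sl == "close"], v[sl == "far"], var.equal = TRUE)$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("elemental classes match exhaustive enumeration on a hand fixture", {
  P <- matrix(1, 10, 10); P[1:5, ] <- 10        # high P in rows 1-5
  Al <- matrix(1, 10, 10); Al[, 1:5] <- 10      # high Al in cols 1-5
  S <- matrix(1, 10, 10)
  Si <- matrix(0, 10, 10)
  dist <- matrix(100 * row(P), 10, 10)          # distance = 100 um x row
  map <- xrfMap(list(P = P, S = S, Al = Al, Si = Si), pixel_size_um = 5)
  phases <- matrix("mixed", 10, 10); phases[1, 1] <- "primary"
  ec <- elementalClasses(map, phases, dist,
                         thresholds = c(P = 5, Al = 5, S = 5),
                         pairs = list(c("P+", "Al-"), c("P+", "Al+")))
  hp_lo <- ec$classes[["P+ & Al-"]]
  expect_equal(hp_lo$n, 25L)                          # rows 1-5, cols 6-10
  expect_equal(hp_lo$mean_distance_um, 300)           # mean of 100..500
  expect_equal(hp_lo$fraction_within_100um, 0.2)      # row 1 only
  hp_hi <- ec$classes[["P+ & Al+"]]
  expect_equal(hp_hi$n, 24L)                          # (1,1) is primary
  expect_equal(hp_hi$mean_distance_um, (300 * 25 - 100) / 24)
  expect_equal(sum(hp_lo$hist$prob), 1)
})

test_that("close-mean thresholds agree with direct pixel-wise comparison", {
  map <- genXRFMaps(seed = 6)
  tr <- syntheticTruth(map)
  ph <- classifyPhases(map, 1000, 1e4)
  ec <- elementalClasses(map, ph, tr$distance_um)
  close_mask <- ph == "mixed" & tr$distance_um <= 50
  expect_equal(unname(ec$thresholds[["P"]]),
               mean(map@elements$P[close_mask]))
  # by definition of the mean, some close pixels sit below the threshold
  expect_true(any(map@elements$P[close_mask] < ec$thresholds[["P"]]))

  expect_error(elementalClasses(map, matrix("air", 160, 160),
                                tr$distance_um),
               class = "mycouptake_empty_class")
})

test_that("plane registration samples the volume consistently", {
  field <- array(seq_len(6 * 5 * 4), c(6, 5, 4))
  map <- xrfMap(list(P = matrix(0, 6, 5), Si = matrix(0, 6, 5)),
                pixel_size_um = 4,
                affine = cbind(diag(3), c(0, 0, 3)))
  expect_equal(registerPlane(map, field), field[, , 3])

  map_shift <- xrfMap(list(P = matrix(0, 6, 5), Si = matrix(0, 6, 5)),
                      pixel_size_um = 4,
                      affine = cbind(diag(3), c(0, 0, 4)))
  expect_equal(registerPlane(map_shift, field), field[, , 4])

  # 90-degree in-plane rotation: exact for nearest-neighbour sampling
  theta <- pi / 2
  A <- cbind(rotation_z(theta), c(6, 0, 2))   # col' = -row offset handled
  sq <- array(seq_len(5 * 5 * 3), c(5, 5, 3))
  map_rot <- xrfMap(list(P = matrix(0, 5, 5), Si = matrix(0, 5, 5)),
                    pixel_size_um = 4, affine = A)
  got <- registerPlane(map_rot, sq)
  manual <- matrix(0, 5, 5)
  for (r in 1:5) for (cc in 1:5) {
    v <- round(A %*% c(r, cc, 0, 1))
    manual[r, cc] <- sq[v[1], v[2], v[3]]
  }
  expect_equal(got, manual)

  oob <- xrfMap(list(P = matrix(0, 6, 5), Si = matrix(0, 6, 5)),
                pixel_size_um = 4, affine = cbind(diag(3), c(0, 0, 10)))
  expect_error(registerPlane(oob, field), class = "mycouptake_out_of_bounds")
})
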